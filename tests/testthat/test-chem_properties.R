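# Partition-coefficient triangle, Koc, and temperature corrections.

test_that("triangle closure matches the tabulated PBDE coefficients", {
  # printed (log_kow, log_kaw, log_koa) triples for the three congeners
  tab <- data.frame(kow = c(6.6, 7.28, 9.97),
                    kaw = c(-1.7, -2.9, -1.9),
                    koa = c(8.3, 10.2, 11.8))
  closed <- triangle_close(tab$kow, tab$kaw)
  expect_true(all(abs(closed - tab$koa) <= 0.1))
  expect_equal(triangle_close(6.6, -1.7), 8.3)
  expect_equal(triangle_close(0, 0), 0)
  expect_equal(triangle_close(9.97, -1.9), 11.87)
  expect_error(triangle_close(NA_real_, 0), "invalid-property")
  expect_error(triangle_close(Inf, 0), "invalid-property")
})

test_that("Koc follows the Karickhoff relation and is monotone in Kow", {
  expect_equal(koc_from_kow(0), 0.41)
  expect_equal(koc_from_kow(6.6), 0.41 * 10^6.6, tolerance = 1e-12)
  expect_equal(koc_from_kow(6.6), 1.632239e6, tolerance = 1e-6)
  expect_gt(koc_from_kow(7.28), koc_from_kow(6.6))
  lk <- sort(runif(20, 0, 11))
  expect_true(all(diff(koc_from_kow(lk)) > 0))
})

test_that("half-life Arrhenius correction behaves as degradation kinetics", {
  # identity cases
  expect_equal(adjust_half_life(1000, 30000, 298.15, 298.15), 1000)
  expect_equal(adjust_half_life(1000, 0, 298.15, 250), 1000)
  # frozen value from independent evaluation of the Arrhenius factor:
  # exp((30000/8.314) * (1/295.15 - 1/298.15)) = 1.13090036
  expect_equal(adjust_half_life(1000, 30000, 298.15, 295.15),
               1130.90036, tolerance = 1e-8)
  # cooling with positive Ea always lengthens the half-life
  expect_true(all(adjust_half_life(50, c(10000, 30000), 298.15, 288.15) > 50))
  # monotone decreasing in temperature for positive Ea
  temps <- seq(270, 320, by = 5)
  hl <- adjust_half_life(1000, 30000, 298.15, temps)
  expect_true(all(diff(hl) < 0))
  expect_error(adjust_half_life(-1, 1e4, 298, 295), "invalid-input")
  expect_error(adjust_half_life(1000, 1e4, 298, -5), "invalid-input")
})

test_that("partition-coefficient van't Hoff correction is exact and invertible", {
  expect_equal(adjust_partition(-1.7, 0, 298.15, 273.15), -1.7)
  expect_equal(adjust_partition(-1.7, 60000, 298.15, 298.15), -1.7)
  # frozen: K multiplied by exp(-(60000/8.314)(1/295.15 - 1/298.15)) = 0.78190018
  got <- adjust_partition(-1.7, 60000, 298.15, 295.15)
  expect_equal(10^got / 10^-1.7, 0.78190018, tolerance = 1e-8)
  # round trip back to the reference temperature
  back <- adjust_partition(got, 60000, 295.15, 298.15)
  expect_equal(back, -1.7, tolerance = 1e-10)
  expect_error(adjust_partition(-1.7, 60000, 0, 298.15), "invalid-input")
})

test_that("chemical records validate inputs and close the triangle", {
  ch <- test_chemical()
  expect_s3_class(ch, "chem_properties")
  expect_equal(ch$log_koa, 8)  # 6 - (-2)
  expect_error(test_chemical(molar_mass = -5), "invalid-property")
  expect_error(test_chemical(half_life = c(air = 0, water = 1, soil = 1,
                                           sediment = 1)), "invalid-property")
  expect_error(test_chemical(half_life = c(air = 10, water = 10)),
               "missing compartment")
  expect_warning(test_chemical(log_koa = 9.2), "departs from")
  expect_silent(ch2 <- test_chemical(log_koa = 8.3))
  expect_equal(ch2$log_koa, 8.3)
})

test_that("temperature re-expression is the identity at the reference point", {
  ch <- test_chemical()
  same <- chemical_at_temperature(ch, 298.15)
  expect_equal(same, ch)
  cooler <- chemical_at_temperature(ch, 295.15)
  expect_true(all(cooler$half_life > ch$half_life))
  expect_equal(cooler$log_kaw, ch$log_kaw)  # zero enthalpy default
  expect_equal(cooler$reference_temperature, 295.15)
})

test_that("chemical tables round-trip losslessly through CSV", {
  chems <- pbde_congeners()
  expect_named(chems, c("BDE-47", "BDE-99", "BDE-209"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chemical_table(chems, path)
  back <- read_chemical_table(path)
  for (nm in names(chems)) {
    expect_equal(back[[nm]]$log_kow, chems[[nm]]$log_kow, tolerance = 1e-7)
    expect_equal(back[[nm]]$half_life, chems[[nm]]$half_life, tolerance = 1e-7)
    expect_equal(back[[nm]]$molar_mass, chems[[nm]]$molar_mass, tolerance = 1e-7)
  }
})
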