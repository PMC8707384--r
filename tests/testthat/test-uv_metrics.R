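test_that("erythemal weights sum to one within 0.001", {
  w <- erythemal_weights()
  expect_equal(nrow(w), 7L)
  expect_true(abs(sum(w$weight) - 1) < 0.001)
  expect_true(all(w$weight > 0))
  expect_equal(attr(w, "cf"), 10)
})

test_that("SPFi closed forms and hand-summed Gaussian oracle", {
  expect_equal(spfi(flat_spectrum(0)), 0)
  expect_equal(spfi(flat_spectrum(1)), 10.002)
  # Gaussian band (305, sigma 10, peak 1): brute-force 5 nm sum
  grid5 <- c(290, 295, 300, 305, 310, 315, 320)
  w <- c(0.0150, 0.0817, 0.2874, 0.3278, 0.1864, 0.0839, 0.0180)
  expected <- 10 * sum(w * exp(-(grid5 - 305)^2 / (2 * 10^2)))
  s <- make_spectrum(data.frame(center = 305, width = 10, peak = 1),
                     noise_sd = 0, step = 1)
  expect_equal(spfi(s), expected, tolerance = 1e-10)
  expect_error(spfi(absorbance_spectrum(300:400, rep(1, 101))), "cover")
})

test_that("SPFi is linear in absorbance", {
  set.seed(11)
  for (i in 1:5) {
    b <- random_bands()
    s1 <- make_spectrum(b, noise_sd = 0, seed = i)
    b2 <- b; b2$peak <- 3.7 * b2$peak
    s2 <- make_spectrum(b2, noise_sd = 0, seed = i)
    expect_equal(spfi(s2), 3.7 * spfi(s1), tolerance = 1e-9)
  }
})

test_that("critical wavelength closed forms", {
  expect_equal(critical_wavelength(flat_spectrum(1))$lambda_c, 389.0)
  # rectangle on [290, 340]: sharp edge resolved by a fine grid
  grid <- seq(290, 400, by = 0.01)
  rect <- absorbance_spectrum(grid, as.numeric(grid <= 340))
  expect_equal(critical_wavelength(rect)$lambda_c, 335.0, tolerance = 0.05)
  expect_error(critical_wavelength(flat_spectrum(0)), "zero")
})

test_that("critical wavelength matches the dense-grid oracle and is scale-invariant", {
  set.seed(42)
  for (i in 1:25) {
    b <- random_bands()
    s <- make_spectrum(b, noise_sd = 0, seed = i)
    lc <- critical_wavelength(s)$lambda_c
    expect_equal(lc, oracle_lambda_c(band_fun(b)), tolerance = 0.05)
    b2 <- b; b2$peak <- 5 * b2$peak
    s2 <- make_spectrum(b2, noise_sd = 0, seed = i)
    expect_equal(critical_wavelength(s2)$lambda_c, lc)
  }
})

test_that("moving absorbance mass into the UV-A region raises lambda_c", {
  uvb <- data.frame(center = 305, width = 10, peak = 1)
  both <- rbind(uvb, data.frame(center = 380, width = 12, peak = 0.8))
  lc1 <- critical_wavelength(make_spectrum(uvb, seed = 1))$lambda_c
  lc2 <- critical_wavelength(make_spectrum(both, seed = 1))$lambda_c
  expect_lt(lc1, 340)
  expect_gt(lc2, lc1)
})

test_that("UVA/UVB ratio closed forms", {
  expect_equal(uva_uvb_ratio(flat_spectrum(1)), 80 / 30, tolerance = 1e-9)
  # UV-B only: zero above 320
  s <- absorbance_spectrum(290:400, ifelse(290:400 <= 320, 1, 0))
  expect_lt(uva_uvb_ratio(s), 0.02)  # only the 320-321 edge triangle remains
  # triangle rising 0 -> 1 over 290-400: analytic ratio of areas
  tri <- absorbance_spectrum(290:400, (290:400 - 290) / 110)
  expect_equal(uva_uvb_ratio(tri), (110^2 - 30^2) / 30^2, tolerance = 1e-9)
  expect_error(uva_uvb_ratio(absorbance_spectrum(290:400, rep(0, 111))), "zero")
})

test_that("metrics agree between the 1 nm and 0.5 nm grids", {
  set.seed(7)
  for (i in 1:5) {
    b <- random_bands()
    s1 <- make_spectrum(b, noise_sd = 0, step = 1, seed = i)
    s05 <- make_spectrum(b, noise_sd = 0, step = 0.5, seed = i)
    expect_equal(spfi(s05), spfi(s1), tolerance = 0.002)
    expect_lt(abs(critical_wavelength(s05)$lambda_c -
                    critical_wavelength(s1)$lambda_c), 0.5)
  }
})

test_that("Boots star rating bands", {
  cases <- rbind(c(0.0, 0), c(0.59, 0), c(0.6, 3), c(0.79, 3),
                 c(0.8, 4), c(0.85, 4), c(0.9, 5), c(1.0, 5), c(2.5, 5))
  for (i in seq_len(nrow(cases)))
    expect_identical(star_rating(cases[i, 1]), as.integer(cases[i, 2]))
  expect_error(star_rating(-0.1), "nonnegative")
})

test_that("broad-spectrum claim boundaries", {
  cfg <- run_config()
  expect_true(broad_spectrum_claim(380, 0.8, cfg))
  expect_false(broad_spectrum_claim(362, 0.7, cfg))   # benchmark-filter-like
  expect_false(broad_spectrum_claim(371, 0.69, cfg))
  expect_false(broad_spectrum_claim(370, 0.9, cfg))   # strict on lambda_c
  expect_true(broad_spectrum_claim(370.1, 0.7, cfg))  # inclusive on ratio
})

test_that("uv_metrics wrapper assembles consistent rows and clips negatives", {
  b <- data.frame(center = c(310, 375), width = c(10, 15), peak = c(0.6, 1.1))
  s <- make_spectrum(b, noise_sd = 0, seed = 1, sample_id = "X1")
  m <- uv_metrics(s)
  expect_equal(m$sample_id, "X1")
  expect_equal(m$stars, star_rating(m$uva_uvb_ratio))
  expect_equal(m$broad_spectrum, m$lambda_c_nm > 370 & m$uva_uvb_ratio >= 0.7)

  neg <- absorbance_spectrum(290:400, c(rep(-0.05, 20), rep(1, 91)))
  expect_warning(v <- spfi(neg), "clipped")
  expect_gte(v, 0)
})
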