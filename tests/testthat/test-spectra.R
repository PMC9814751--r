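test_that("a noiseless Gaussian is recovered with its analytic area", {
  sim <- synth_spectrum(data.frame(center = 418, height = 1, fwhm = 12))
  f <- fit_main_peak(sim$spectrum$wavelength, sim$spectrum$absorbance)
  expect_true(f$peak_found)
  expect_equal(f$lambda_max, 418, tolerance = 0.1 / 418)
  expect_equal(f$intensity, 1.0, tolerance = 0.01)
  expect_equal(f$fwhm, 12, tolerance = 0.1 / 12)
  expect_equal(f$area, 1.0 * 12 * sqrt(pi / (4 * log(2))),
               tolerance = 0.01)                 # 12.77 absorbance*nm
  expect_equal(f$area, sim$truth$area, tolerance = 0.01)
})

test_that("flat and sub-threshold spectra are declared peakless", {
  wl <- seq(350, 550, 0.5)
  f0 <- fit_main_peak(wl, rep(0, length(wl)))
  expect_false(f0$peak_found)
  expect_true(is.na(f0$lambda_max) && is.na(f0$area))
  # below the absolute absorbance floor
  tiny <- synth_spectrum(data.frame(center = 420, height = 0.003, fwhm = 12))
  expect_false(fit_main_peak(tiny$spectrum$wavelength,
                             tiny$spectrum$absorbance)$peak_found)
  # pure noise: fitted height fails the SNR criterion
  noise <- synth_spectrum(data.frame(center = numeric(0), height = numeric(0),
                                     fwhm = numeric(0))[0, ],
                          noise_sd = 0.02, seed = 4)
  expect_false(fit_main_peak(noise$spectrum$wavelength,
                             noise$spectrum$absorbance)$peak_found)
  # window contracts
  expect_error(fit_main_peak(wl, rep(0, length(wl)), window = c(300, 470)),
               "outside")
  expect_error(fit_main_peak(seq(380, 470, 30), rep(1, 4)), "10 grid points")
})

test_that("the shoulder is separated and the main-component area survives", {
  sim <- synth_spectrum(data.frame(center = c(418, 403),
                                   height = c(1, 0.3), fwhm = c(12, 14)))
  f <- fit_main_peak(sim$spectrum$wavelength, sim$spectrum$absorbance)
  expect_true(f$peak_found)
  # single-Gaussian width is inflated by the shoulder
  expect_gt(f$fwhm, 12)
  # but the two-Gaussian main component recovers the analytic area within 5%
  expect_equal(f$area, sim$truth$area, tolerance = 0.05)
  expect_equal(nrow(f$components), 2L)
  main <- f$components[f$components$role == "main", ]
  shoulder <- f$components[f$components$role == "shoulder", ]
  expect_lt(shoulder$center, main$center)
})

test_that("random single peaks are recovered within tight tolerances", {
  set.seed(99)
  n_cases <- 40
  centers <- runif(n_cases, 400, 440)
  fwhms <- runif(n_cases, 8, 40)
  for (i in seq_len(n_cases)) {
    sim <- synth_spectrum(data.frame(center = centers[i], height = 1,
                                     fwhm = fwhms[i]),
                          noise_sd = 1 / 50, seed = i)   # SNR 50
    f <- fit_main_peak(sim$spectrum$wavelength, sim$spectrum$absorbance)
    expect_true(f$peak_found)
    expect_lt(abs(f$lambda_max - centers[i]), 0.5)
    expect_lt(abs(f$fwhm - fwhms[i]) / fwhms[i], 0.05)
    expect_lt(abs(f$area - sim$truth$area) / sim$truth$area, 0.05)
  }
})

test_that("relative indicators are per-molecule normalized and scale-invariant", {
  fits <- data.frame(
    molecule_id = rep("m1", 3), solvent_id = c("s1", "s2", "s3"),
    peak_found = c(TRUE, TRUE, FALSE),
    fwhm = c(10, 20, NA), area = c(5, 20, NA)
  )
  out <- relative_indicators(fits)
  expect_equal(out$fwhm_r, c(1, 0.5, 0))     # FWHM_min attains 1; 2x -> 0.5
  expect_equal(out$area_r, c(0.25, 1, 0))
  expect_true(all(out$fwhm_r >= 0 & out$fwhm_r <= 1))

  # all-insoluble molecule: zeros plus a warning
  allna <- data.frame(molecule_id = "m2", solvent_id = paste0("s", 1:16),
                      peak_found = FALSE, fwhm = NA_real_, area = NA_real_)
  expect_warning(out2 <- relative_indicators(allna), "no peak")
  expect_true(all(out2$fwhm_r == 0 & out2$area_r == 0))

  # scaling all absorbances by c > 0 changes intensity/area but not the
  # relative indicators
  base <- lapply(c(1, 7.5), function(scale) {
    fits <- do.call(rbind, lapply(1:3, function(s) {
      sim <- synth_spectrum(data.frame(center = 410 + 5 * s, height = 1,
                                       fwhm = 8 + 4 * s))
      f <- fit_main_peak(sim$spectrum$wavelength,
                         scale * sim$spectrum$absorbance)
      data.frame(molecule_id = "m", solvent_id = paste0("s", s),
                 peak_found = f$peak_found, fwhm = f$fwhm, area = f$area)
    }))
    relative_indicators(fits)
  })
  expect_equal(base[[1]]$fwhm_r, base[[2]]$fwhm_r, tolerance = 1e-6)
  expect_equal(base[[1]]$area_r, base[[2]]$area_r, tolerance = 1e-6)
})

test_that("K-means categorization recovers planted blobs with ordered labels", {
  set.seed(1)
  centers <- rbind(c(0, 0), c(0.3, 0.9), c(0.9, 0.3), c(0.8, 0.8), c(1, 1))
  blob <- do.call(rbind, lapply(1:5, function(b) {
    data.frame(blob = b,
               fwhm_r = pmin(pmax(centers[b, 1] + rnorm(30, 0, 0.02), 0), 1.2),
               area_r = pmin(pmax(centers[b, 2] + rnorm(30, 0, 0.02), 0), 1.2))
  }))
  blob$peak_found <- TRUE
  out <- categorize(blob, k = 5, seed = 7)
  # planted blobs map to single categories; the (1,1) blob is category 4
  per_blob <- tapply(out$category, out$blob, function(x) length(unique(x)))
  expect_true(all(per_blob == 1))
  expect_equal(unique(out$category[out$blob == 5]), 4L)
  expect_equal(unique(out$category[out$blob == 1]), 0L)
  expect_true(all(out$label_good == (out$category %in% c(3, 4))))

  # duplicating a point changes no category
  dup <- rbind(blob, blob[17, ])
  out_dup <- categorize(dup, k = 5, seed = 7)
  expect_equal(out_dup$category[seq_len(nrow(blob))], out$category)

  # forced category 0 for no-peak rows regardless of clustering
  blob2 <- blob
  blob2$peak_found[1:10] <- FALSE
  blob2$fwhm_r[1:10] <- 0
  blob2$area_r[1:10] <- 0
  out2 <- categorize(blob2, k = 5, seed = 7)
  expect_true(all(out2$category[1:10] == 0))

  expect_error(categorize(blob[1:4, ], k = 5, seed = 1), "smaller k")
})

test_that("the spectrum table pipeline keeps per-pair bookkeeping straight", {
  # 2 molecules x 3 solvents; one flat spectrum (m2 insoluble in s3)
  design <- expand.grid(mol = c("m1", "m2"), solv = c("s1", "s2", "s3"),
                        stringsAsFactors = FALSE)
  specs <- do.call(rbind, lapply(seq_len(nrow(design)), function(r) {
    flat <- design$mol[r] == "m2" & design$solv[r] == "s3"
    comp <- if (flat) {
      data.frame(center = numeric(0), height = numeric(0), fwhm = numeric(0))
    } else {
      data.frame(center = 400 + 8 * r, height = 0.5 + 0.1 * r,
                 fwhm = 9 + 3 * r)
    }
    sim <- synth_spectrum(comp, noise_sd = 0.002, seed = r)
    data.frame(molecule_id = design$mol[r], solvent_id = design$solv[r],
               sim$spectrum)
  }))
  expect_message(
    evals <- indicator_table(specs, k = 5, seed = 3, include_nopeak = TRUE),
    "6 evaluations"
  )
  expect_equal(nrow(evals), 6L)
  expect_equal(attr(evals, "n_peak_found"), 5L)
  expect_equal(attr(evals, "n_no_peak"), 1L)
  expect_equal(sum(evals$category == 0), 1L)
  expect_gte(sum(evals$category == 0), sum(!evals$peak_found))
})

test_that("eV helpers agree with the photon-energy relation", {
  expect_equal(nm_to_ev(418), 1239.842 / 418)
  w_ev <- fwhm_nm_to_ev(12, 418)
  expect_equal(w_ev, 1239.842 / 412 - 1239.842 / 424, tolerance = 1e-12)
  expect_equal(w_ev, 0.085, tolerance = 0.01)   # Soret widths are ~0.1 eV
})
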