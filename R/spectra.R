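# ---------------------------------------------------------------------------
# UV-Vis spectrum reduction: Gaussian peak fitting, relative solubility
# indicators, K-means categorization of molecule-solvent pairs
# ---------------------------------------------------------------------------

.GAUSS_AREA_C <- sqrt(pi / (4 * log(2)))  # area = height * fwhm * this

#' Gaussian peak profile parameterized by height, center and FWHM
#'
#' @param x wavelength grid (nm).
#' @param height peak height (absorbance).
#' @param center peak position (nm).
#' @param fwhm full width at half maximum (nm).
#' @return absorbance values.
#' @export
gauss_peak <- function(x, height, center, fwhm) {
  height * exp(-4 * log(2) * ((x - center) / fwhm)^2)
}

#' Photon energy (eV) at a wavelength (nm)
#'
#' `E = 1239.842 / lambda`; useful to express peak widths in eV.
#'
#' @param nm wavelength(s) in nm.
#' @return energy in eV.
#' @export
nm_to_ev <- function(nm) 1239.842 / nm

#' FWHM converted from nm to eV at a given peak center
#'
#' @param fwhm_nm width in nm.
#' @param center_nm peak center in nm.
#' @return width in eV, `E(center - w/2) - E(center + w/2)`.
#' @export
fwhm_nm_to_ev <- function(fwhm_nm, center_nm) {
  nm_to_ev(center_nm - fwhm_nm / 2) - nm_to_ev(center_nm + fwhm_nm / 2)
}

.no_peak_fit <- function(reason, rms = NA_real_) {
  structure(
    list(peak_found = FALSE, lambda_max = NA_real_, intensity = NA_real_,
         fwhm = NA_real_, area = NA_real_, components = NULL,
         fit_residual = rms, reason = reason),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  if (!x$peak_found) {
    cat("<peak_fit> no peak (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "<peak_fit> lambda_max %.1f nm, intensity %.3f, fwhm %.1f nm, area %.2f\n",
      x$lambda_max, x$intensity, x$fwhm, x$area))
  }
  invisible(x)
}

# initial FWHM estimate: width of the region above half max, interpolated
.init_fwhm <- function(x, y, imax) {
  half <- y[imax] / 2
  above <- y >= half
  lo <- x[min(which(above))]
  hi <- x[max(which(above))]
  w <- hi - lo
  if (!is.finite(w) || w <= 0) w <- (max(x) - min(x)) / 10
  w
}

#' Fit the main absorption peak of one spectrum
#'
#' Reduces a baseline-subtracted UV-Vis spectrum to the four solubility
#' indicators. A single-Gaussian least-squares fit inside the search window
#' gives the peak position (`lambda_max`), height (`intensity`) and width
#' (`fwhm`); a two-Gaussian fit (main component plus a shorter-wavelength
#' shoulder) gives `area` as the analytic area of the main component,
#' `height * fwhm * sqrt(pi / (4 ln 2))`. A spectrum is declared peakless
#' when the fit fails to converge, or the fitted height falls below
#' `height_floor` or below `snr_min` times the RMS fit residual.
#'
#' @param wavelength ascending wavelength grid (nm).
#' @param absorbance absorbance values (same length).
#' @param window numeric length-2 search window in nm (default the Soret
#'   region, 380-470 nm).
#' @param height_floor absolute absorbance floor for peak detection
#'   (default 0.005).
#' @param snr_min minimal height-to-residual ratio (default 5).
#' @param shoulder_gain acceptance rule for the two-Gaussian decomposition:
#'   it is used for the area only when its RMS residual falls below
#'   `shoulder_gain` times the single-Gaussian RMS (default 0.7); otherwise
#'   the area comes from the single fit. Protects a plain Gaussian-plus-noise
#'   peak from having area leak into a spurious second component.
#' @return a `peak_fit` object; indicator fields are `NA` when no peak is
#'   found. `components` holds the fitted Gaussian parameter sets.
#' @export
fit_main_peak <- function(wavelength, absorbance, window = c(380, 470),
                          height_floor = 0.005, snr_min = 5,
                          shoulder_gain = 0.7) {
  stopifnot(length(wavelength) == length(absorbance),
            !is.unsorted(wavelength, strictly = TRUE),
            all(is.finite(absorbance)))
  if (window[1] < min(wavelength) || window[2] > max(wavelength)) {
    stop("search window outside the spectrum range")
  }
  sel <- wavelength >= window[1] & wavelength <= window[2]
  if (sum(sel) < 10) stop("fewer than 10 grid points inside the window")
  x <- wavelength[sel]
  y <- absorbance[sel]
  imax <- which.max(y)
  h0 <- y[imax]
  if (h0 <= 0) return(.no_peak_fit("non-positive maximum", rms = sqrt(mean(y^2))))
  mu0 <- x[imax]
  w0 <- .init_fwhm(x, y, imax)
  span <- diff(window)

  fit1 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ gauss_peak(x, h, mu, w),
      start = list(h = h0, mu = mu0, w = w0),
      lower = c(h = 0, mu = window[1], w = 0.5),
      upper = c(h = 10 * max(h0, 1e-6), mu = window[2], w = 3 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit1)) return(.no_peak_fit("single-Gaussian fit failed"))
  p1 <- as.list(coef(fit1))
  rms <- sqrt(mean(residuals(fit1)^2))
  if (p1$h < height_floor) return(.no_peak_fit("below absorbance floor", rms))
  if (p1$h < snr_min * rms) return(.no_peak_fit("below signal-to-noise floor", rms))

  # two-Gaussian fit for the area: main from the single fit, shoulder
  # initialized 15 nm blue-shifted at 30% height and constrained to the
  # shorter-wavelength side of the main component
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ gauss_peak(x, h1, mu1, w1) + gauss_peak(x, h2, mu2, w2),
      start = list(h1 = p1$h, mu1 = p1$mu, w1 = p1$w,
                   h2 = 0.3 * p1$h, mu2 = max(p1$mu - 15, window[1]),
                   w2 = p1$w),
      lower = c(h1 = 0, mu1 = p1$mu - 5, w1 = 0.5,
                h2 = 0, mu2 = window[1], w2 = 0.5),
      upper = c(h1 = 10 * max(h0, 1e-6), mu1 = window[2], w1 = 3 * span,
                h2 = 10 * max(h0, 1e-6), mu2 = p1$mu, w2 = 3 * span),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  # accept the two-component decomposition only when it clearly improves on
  # the single Gaussian (a genuine shoulder); otherwise the second component
  # is fitting noise and would steal area from the main peak
  rms2 <- if (!is.null(fit2)) sqrt(mean(residuals(fit2)^2)) else Inf
  if (!is.null(fit2) && rms2 < shoulder_gain * rms) {
    p2 <- as.list(coef(fit2))
    comps <- data.frame(
      role = c("main", "shoulder"),
      height = c(p2$h1, p2$h2), center = c(p2$mu1, p2$mu2),
      fwhm = c(p2$w1, p2$w2)
    )
    area <- p2$h1 * p2$w1 * .GAUSS_AREA_C
  } else {
    comps <- data.frame(role = "main", height = p1$h, center = p1$mu,
                        fwhm = p1$w)
    area <- p1$h * p1$w * .GAUSS_AREA_C
  }
  structure(
    list(peak_found = TRUE, lambda_max = p1$mu, intensity = p1$h,
         fwhm = p1$w, area = area, components = comps,
         fit_residual = rms, reason = NA_character_),
    class = "peak_fit"
  )
}

#' Per-molecule relative indicators from peak fits
#'
#' Adds `fwhm_r = FWHM_min / FWHM` and `area_r = Area / Area_max` to a table
#' of per-pair peak fits, where the extrema are taken per molecule over the
#' solvents in which a peak was found. Both indicators lie in \[0, 1\] and
#' equal 1 in the molecule's most suitable solvent; no-peak entries get
#' (0, 0). A molecule with no detected peak in any solvent gets all zeros,
#' with a warning.
#'
#' @param fits data.frame with columns `molecule_id`, `solvent_id`,
#'   `peak_found`, `fwhm`, `area` (e.g. built by [indicator_table()]).
#' @return the input with `fwhm_r` and `area_r` columns appended.
#' @export
relative_indicators <- function(fits) {
  stopifnot(all(c("molecule_id", "peak_found", "fwhm", "area") %in%
                  names(fits)))
  fits$fwhm_r <- 0
  fits$area_r <- 0
  for (mol in unique(fits$molecule_id)) {
    rows <- which(fits$molecule_id == mol)
    found <- rows[fits$peak_found[rows]]
    if (!length(found)) {
      warning("molecule ", mol, ": no peak found in any solvent; ",
              "indicators set to 0")
      next
    }
    fwhm_min <- min(fits$fwhm[found])
    area_max <- max(fits$area[found])
    fits$fwhm_r[found] <- fwhm_min / fits$fwhm[found]
    fits$area_r[found] <- fits$area[found] / area_max
  }
  fits
}

#' Categorize molecule-solvent pairs by K-means on the relative indicators
#'
#' Clusters the (fwhm_r, area_r) points of peak-found pairs by K-means and
#' maps clusters to ordinal categories 0..k-1 by ascending centroid sum
#' (fwhm_r + area_r), so that category 0 is the origin cluster and category
#' k-1 the sharp-and-large corner near (1, 1). Pairs without a detected peak
#' are forced to category 0 (insoluble). The good-solvent label is category
#' 3 or 4 under the default k = 5.
#'
#' @param evals data.frame with `peak_found`, `fwhm_r`, `area_r`.
#' @param k number of clusters (default 5).
#' @param seed RNG seed for the K-means restarts.
#' @param include_nopeak cluster the (0,0) no-peak points too instead of
#'   assigning them a priori (default FALSE).
#' @param good_categories categories labeled as good solvents
#'   (default `c(3, 4)`).
#' @return the input with integer `category` and logical `label_good`
#'   appended.
#' @export
categorize <- function(evals, k = 5, seed = 0, include_nopeak = FALSE,
                       good_categories = c(3, 4)) {
  stopifnot(all(c("peak_found", "fwhm_r", "area_r") %in% names(evals)))
  use <- if (include_nopeak) seq_len(nrow(evals)) else which(evals$peak_found)
  pts <- cbind(evals$fwhm_r[use], evals$area_r[use])
  if (nrow(unique(pts)) < k) {
    stop("fewer than k = ", k, " distinct indicator points; use a smaller k")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- kmeans(pts, centers = k, nstart = 25, iter.max = 100)
  cat_of_cluster <- integer(k)
  cat_of_cluster[order(rowSums(km$centers))] <- 0:(k - 1)
  evals$category <- 0L
  evals$category[use] <- cat_of_cluster[km$cluster]
  evals$category[!evals$peak_found] <- 0L
  evals$label_good <- evals$category %in% good_categories
  evals
}

#' Reduce a full spectrum set to the evaluation table
#'
#' Pipeline composition over a molecule x solvent design:
#' [fit_main_peak()] per spectrum, [relative_indicators()] per molecule,
#' [categorize()] over all pairs. One row is emitted per molecule-solvent
#' pair; the counts of peak-found and peakless spectra are reported in a
#' message and as attributes.
#'
#' @param spectra long-format data.frame with columns `molecule_id`,
#'   `solvent_id`, `wavelength`, `absorbance`.
#' @param window,height_floor,snr_min passed to [fit_main_peak()].
#' @param k,seed,include_nopeak passed to [categorize()].
#' @return evaluation table: one row per pair with the four indicators,
#'   `fwhm_r`, `area_r`, `category`, `label_good`. Attributes
#'   `"n_peak_found"` and `"n_no_peak"` carry the counts.
#' @export
indicator_table <- function(spectra, window = c(380, 470), k = 5, seed = 0,
                            height_floor = 0.005, snr_min = 5,
                            include_nopeak = FALSE) {
  stopifnot(all(c("molecule_id", "solvent_id", "wavelength", "absorbance")
                %in% names(spectra)))
  key <- interaction(spectra$molecule_id, spectra$solvent_id, drop = TRUE)
  parts <- split(spectra, key)
  rows <- lapply(parts, function(sp) {
    sp <- sp[order(sp$wavelength), ]
    fit <- fit_main_peak(sp$wavelength, sp$absorbance, window = window,
                         height_floor = height_floor, snr_min = snr_min)
    data.frame(
      molecule_id = sp$molecule_id[1], solvent_id = sp$solvent_id[1],
      peak_found = fit$peak_found, lambda_max = fit$lambda_max,
      intensity = fit$intensity, fwhm = fit$fwhm, area = fit$area,
      stringsAsFactors = FALSE
    )
  })
  evals <- do.call(rbind, rows)
  rownames(evals) <- NULL
  evals <- evals[order(evals$molecule_id, evals$solvent_id), ]
  rownames(evals) <- NULL
  evals <- relative_indicators(evals)
  evals <- categorize(evals, k = k, seed = seed,
                      include_nopeak = include_nopeak)
  n_found <- sum(evals$peak_found)
  message(nrow(evals), " evaluations: main peak detected for ", n_found,
          ", no peak for ", nrow(evals) - n_found)
  attr(evals, "n_peak_found") <- n_found
  attr(evals, "n_no_peak") <- nrow(evals) - n_found
  evals
}

#' The 16-solvent panel with dielectric constants
#'
#' Solvents S1-S16 spanning dielectric constants from water (78.4) down to
#' n-hexane (1.88); epsilon values are the polarizable-continuum (SCRF)
#' solvent-model constants.
#'
#' @return data.frame with columns `id`, `name`, `smiles`, `epsilon`.
#' @export
solvent_table <- function() {
  data.frame(
    id = paste0("S", 1:16),
    name = c("water", "dimethyl sulfoxide", "N,N-dimethylformamide",
             "acetonitrile", "methanol", "ethanol", "acetone", "2-propanol",
             "dichloromethane", "1,2-dichloroethane", "tetrahydrofuran",
             "chloroform", "toluene", "1,4-dioxane", "cyclohexane",
             "n-hexane"),
    smiles = c("O", "CS(=O)C", "CN(C)C=O", "CC#N", "CO", "CCO", "CC(=O)C",
               "CC(C)O", "ClCCl", "ClCCCl", "C1CCOC1", "ClC(Cl)Cl",
               "Cc1ccccc1", "C1COCCO1", "C1CCCCC1", "CCCCCC"),
    epsilon = c(78.36, 46.83, 37.22, 35.69, 32.61, 24.85, 20.49, 19.26,
                8.93, 10.13, 7.43, 4.71, 2.37, 2.21, 2.02, 1.88),
    stringsAsFactors = FALSE
  )
}
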