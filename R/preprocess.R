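#' Spectral preprocessing
#'
#' Transforms raw frequency-domain spectra into a metabolite quantification
#' table.  The serum protocol is: chemical-shift referencing to the left
#' alanine line at 1.47 ppm, cropping to 0.1--4.2 ppm, and peak-window
#' integration.  The tissue protocol is: cropping to 1.4--4.70 ppm,
#' referencing to creatine at 3.03 ppm, asymmetric least squares baseline
#' correction (lambda = 1e7, p = 1e-4, lowest point anchored to zero),
#' exclusion of the lipid and ethanol windows, total-area normalization,
#' integration, and a log10 transform.
#'
#' @name preprocessing
NULL

#' Reference the chemical-shift axis to a known peak
#'
#' Translates the ppm axis so that the intensity maximum found within
#' `target_ppm +/- search_halfwidth` sits exactly at `target_ppm`.
#' Intensities are unchanged.  If the maximum is not unique, the tie is
#' broken toward the point nearest the target and a warning is issued.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param target_ppm Reference position (ppm), e.g. 1.47 for the left
#'   alanine line in serum or 3.03 for creatine in tissue.
#' @param search_halfwidth Half-width of the search window (ppm).
#' @return The referenced [nmr_spectrum()].
#' @export
reference_shift <- function(spectrum, target_ppm, search_halfwidth = 0.1) {
  in_win <- which(abs(spectrum$ppm - target_ppm) <= search_halfwidth)
  if (length(in_win) < 3) {
    stop("reference search window contains fewer than 3 axis points")
  }
  y <- spectrum$intensity[in_win]
  hits <- in_win[which(y == max(y))]
  if (length(hits) > 1) {
    warning("flat maximum in reference window; tie broken toward target")
    hits <- hits[which.min(abs(spectrum$ppm[hits] - target_ppm))]
  }
  apex <- spectrum$ppm[hits[1]]
  nmr_spectrum(spectrum$ppm - (apex - target_ppm), spectrum$intensity,
               spectrum$sample_id)
}

#' Crop a spectrum to a retained chemical-shift window
#'
#' Keeps exactly the axis points with `lo <= ppm <= hi` (closed interval).
#'
#' @param spectrum An [nmr_spectrum()].
#' @param lo,hi Window bounds (ppm), `lo < hi`.
#' @return The cropped [nmr_spectrum()].
#' @export
crop_region <- function(spectrum, lo, hi) {
  if (lo >= hi) stop("crop window must satisfy lo < hi")
  keep <- spectrum$ppm >= lo & spectrum$ppm <= hi
  if (sum(keep) == 0) stop("crop window contains no axis points")
  nmr_spectrum(spectrum$ppm[keep], spectrum$intensity[keep],
               spectrum$sample_id)
}

#' Remove excluded chemical-shift windows
#'
#' Drops all axis points falling inside any of the given closed windows
#' (lipid and ethanol regions in the tissue protocol); the order of the
#' remaining points is preserved.  An empty window list is the identity.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param windows Two-column matrix (or data frame) of `(lo, hi)` bounds,
#'   one row per excluded window; see [tissue_exclusion_windows()].
#' @return The gapped [nmr_spectrum()].
#' @export
exclude_regions <- function(spectrum, windows) {
  if (is.null(windows) || nrow(windows) == 0) return(spectrum)
  windows <- as.matrix(windows)
  drop <- rep(FALSE, length(spectrum$ppm))
  for (k in seq_len(nrow(windows))) {
    drop <- drop | (spectrum$ppm >= windows[k, 1] &
                      spectrum$ppm <= windows[k, 2])
  }
  if (all(!drop)) return(spectrum)
  nmr_spectrum(spectrum$ppm[!drop], spectrum$intensity[!drop],
               spectrum$sample_id)
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth baseline `z` minimizing
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, differences = 2))^2)`
#' with asymmetric weights iterated as `w_i = p` where `y_i > z_i` and
#' `1 - p` elsewhere (the Whittaker-smoother formulation of asymmetric
#' least squares).  Iteration stops after `n_iter` rounds or when the
#' relative change in `z` falls below 1e-8.  The corrected spectrum is
#' `y - z`, optionally shifted so its minimum is exactly zero.
#'
#' @param spectrum An [nmr_spectrum()] with at least 4 points.
#' @param lam Smoothness penalty lambda (default 1e7).
#' @param p Asymmetry weight (default 1e-4).
#' @param n_iter Maximum reweighting iterations (default 10).
#' @param anchor_zero If `TRUE`, subtract the post-correction minimum so
#'   the lowest point of the corrected spectrum is zero.
#' @return List with elements `baseline` and `corrected`, both
#'   [nmr_spectrum()] objects.
#' @export
als_baseline_correct <- function(spectrum, lam = 1e7, p = 1e-4,
                                 n_iter = 10, anchor_zero = TRUE) {
  if (lam <= 0) stop("lam must be > 0")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (n_iter < 1) stop("n_iter must be >= 1")
  y <- spectrum$intensity
  if (any(!is.finite(y))) stop("non-finite intensities")
  n <- length(y)
  if (n < 4) stop("spectrum too short for a second-difference penalty")
  d <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  dtd <- lam * Matrix::crossprod(d)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    a <- dtd + Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(a, w * y))
    rel <- sqrt(sum((z_new - z)^2)) / max(sqrt(sum(z^2)), 1e-300)
    z <- z_new
    w <- ifelse(y > z, p, 1 - p)
    if (it > 1 && rel < 1e-8) break
  }
  corrected <- y - z
  if (anchor_zero) corrected <- corrected - min(corrected)
  list(
    baseline = nmr_spectrum(spectrum$ppm, z, spectrum$sample_id),
    corrected = nmr_spectrum(spectrum$ppm, corrected, spectrum$sample_id)
  )
}

#' Normalize a spectrum to unit total area
#'
#' Scales the intensities so the trapezoid area over the (possibly gapped)
#' axis equals one; axis gaps left by [exclude_regions()] contribute no
#' area.
#'
#' @param spectrum An [nmr_spectrum()].
#' @return The normalized [nmr_spectrum()].
#' @export
total_area_normalize <- function(spectrum) {
  area <- .trapz_gapped(spectrum$ppm, spectrum$intensity)
  if (!is.finite(area) || area <= 0) {
    stop("total spectrum area must be positive for normalization")
  }
  nmr_spectrum(spectrum$ppm, spectrum$intensity / area, spectrum$sample_id)
}

#' Default integration windows for a metabolite library
#'
#' One window per metabolite, spanning all its library peaks plus
#' `k_halfwidths` half-widths on each side.  Overlapping windows are a
#' validation error: the default libraries are laid out so their windows
#' are disjoint.
#'
#' @param library A metabolite library data frame.
#' @param k_halfwidths Margin in units of the peak half-width (default 3).
#' @return Data frame `metabolite`, `lo_ppm`, `hi_ppm`.
#' @export
default_windows <- function(library, k_halfwidths = 3) {
  validate_library(library)
  mets <- library_metabolites(library)
  win <- do.call(rbind, lapply(mets, function(m) {
    rows <- library[library$name == m, ]
    data.frame(
      metabolite = m,
      lo_ppm = min(rows$center_ppm) - k_halfwidths * max(rows$halfwidth_ppm),
      hi_ppm = max(rows$center_ppm) + k_halfwidths * max(rows$halfwidth_ppm),
      stringsAsFactors = FALSE
    )
  }))
  o <- order(win$lo_ppm)
  s <- win[o, ]
  overlap <- which(s$lo_ppm[-1] <= s$hi_ppm[-nrow(s)])
  if (length(overlap) > 0) {
    stop("overlapping integration windows: ",
         paste(s$metabolite[overlap], s$metabolite[overlap + 1],
               sep = "/", collapse = ", "))
  }
  win
}

#' Integrate metabolite windows
#'
#' Trapezoid integral of the intensity over each `[lo, hi]` window,
#' returned keyed by metabolite name.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param windows Data frame `metabolite`, `lo_ppm`, `hi_ppm`.
#' @return Named numeric vector of areas.
#' @export
integrate_windows <- function(spectrum, windows) {
  o <- order(spectrum$ppm)
  x <- spectrum$ppm[o]; y <- spectrum$intensity[o]
  out <- numeric(nrow(windows))
  names(out) <- windows$metabolite
  for (k in seq_len(nrow(windows))) {
    sel <- x >= windows$lo_ppm[k] & x <= windows$hi_ppm[k]
    if (sum(sel) < 2) {
      stop("integration window for '", windows$metabolite[k],
           "' contains fewer than 2 axis points")
    }
    xi <- x[sel]; yi <- y[sel]
    out[k] <- sum(diff(xi) * (yi[-length(yi)] + yi[-1]) / 2)
  }
  out
}

#' Log10-transform a quantification table
#'
#' @param table Numeric matrix or data frame of positive integrated areas
#'   (samples x metabolites).
#' @return The elementwise log10 of the table.
#' @export
log10_transform <- function(table) {
  m <- as.matrix(table)
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "nonpositive area for sample '%s', metabolite '%s'",
      rownames(m)[bad[1, 1]] %||% bad[1, 1],
      colnames(m)[bad[1, 2]] %||% bad[1, 2]
    ))
  }
  log10(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess a set of spectra into a quantification table
#'
#' Applies the full serum or tissue protocol (see [preprocessing]) to each
#' spectrum and stacks the integrated areas into a samples-by-metabolites
#' matrix.  Serum areas are returned raw; tissue areas are total-area
#' normalized and log10 transformed.
#'
#' @param spectra List of [nmr_spectrum()] objects (typically
#'   `cohort$spectra`).
#' @param protocol `"serum"` or `"tissue"`.
#' @param windows Integration windows; default derived from the matching
#'   default library.
#' @param normalize Optional total-area normalization for the serum
#'   protocol (the tissue protocol always normalizes); default off, since
#'   serum spectra arrive already phased and baseline-corrected upstream.
#' @param baseline_params List overriding the tissue ALS parameters
#'   (`lam`, `p`, `n_iter`).
#' @return Numeric matrix (samples x metabolites) with sample ids as row
#'   names.
#' @export
preprocess_spectra <- function(spectra, protocol = c("serum", "tissue"),
                               windows = NULL, normalize = FALSE,
                               baseline_params = list()) {
  protocol <- match.arg(protocol)
  if (is.null(windows)) {
    windows <- default_windows(
      if (protocol == "serum") build_default_serum_library()
      else build_default_tissue_library()
    )
  }
  bp <- utils::modifyList(list(lam = 1e7, p = 1e-4, n_iter = 10),
                          baseline_params)
  one <- function(sp) {
    if (protocol == "serum") {
      sp <- reference_shift(sp, 1.47, 0.1)
      sp <- crop_region(sp, 0.1, 4.2)
      if (normalize) sp <- total_area_normalize(sp)
    } else {
      sp <- crop_region(sp, 1.4, 4.70)
      sp <- reference_shift(sp, 3.03, 0.1)
      sp <- als_baseline_correct(sp, lam = bp$lam, p = bp$p,
                                 n_iter = bp$n_iter)$corrected
      sp <- exclude_regions(sp, tissue_exclusion_windows())
      sp <- total_area_normalize(sp)
    }
    integrate_windows(sp, windows)
  }
  rows <- lapply(seq_along(spectra), function(i) {
    tryCatch(one(spectra[[i]]), error = function(e) {
      stop("preprocessing failed for sample '",
           spectra[[i]]$sample_id %||% i, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  quant <- do.call(rbind, rows)
  rownames(quant) <- vapply(spectra, function(s) s$sample_id, character(1))
  if (protocol == "tissue") quant <- log10_transform(quant)
  quant
}
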