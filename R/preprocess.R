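# Generic preprocessing: fluorescence baseline removal and band
# normalization. These stand upstream of the modelling code, which by
# default consumes baseline-corrected but UNnormalized spectra (band
# normalization is a visualization aid, not a modelling step).

#' Iteratively reweighted polynomial baseline subtraction
#'
#' Fits a polynomial that hugs the local minima of the spectrum (the
#' modified-polyfit scheme: after each fit, the working curve is clipped
#' to the pointwise minimum of itself and the fit, so peaks are
#' progressively excluded from the baseline estimate) and subtracts it.
#' Peak positions are preserved; applying the operation twice changes
#' nearly nothing.
#'
#' @param s a [raman_spectrum()].
#' @param degree polynomial degree (default 5); must satisfy
#'   `degree < length(axis)/10`.
#' @param iterations number of clip-and-refit passes (default 20).
#' @return the baseline-subtracted spectrum; the fitted baseline is
#'   attached as attribute `"baseline"`.
#' @export
subtract_baseline <- function(s, degree = 5, iterations = 20) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (any(!is.finite(s$intensities)))
    stop("intensities must be finite", call. = FALSE)
  n <- length(s$axis)
  if (degree < 0 || degree >= n / 10)
    stop("degree must be >= 0 and < length(axis)/10", call. = FALSE)
  x <- as.numeric(s$axis)
  u <- (x - x[1]) / (x[n] - x[1])  # scale to [0,1] for conditioning
  work <- s$intensities
  basis <- outer(u, 0:degree, `^`)
  qrb <- qr(basis)
  base <- work
  for (it in seq_len(iterations)) {
    base <- basis %*% qr.coef(qrb, work)
    work <- pmin(work, base)
  }
  out <- raman_spectrum(s$axis, s$intensities - as.numeric(base), s$meta)
  attr(out, "baseline") <- as.numeric(base)
  out
}

#' Scale a spectrum so a band's maximum equals one
#'
#' Standard display normalizations: phosphate-band (~960 cm^-1)
#' normalization for comparing bone spectra, CH2-band (~1450 cm^-1)
#' normalization for comparing transcutaneous spectra. Purely a
#' visualization aid; the regression models consume unnormalized spectra.
#'
#' @param s a [raman_spectrum()].
#' @param band a [band_definition()] or numeric `c(lo, hi)` window in
#'   cm^-1.
#' @return the scaled spectrum, with the applied scale factor attached as
#'   attribute `"scale_factor"`.
#' @export
normalize_to_band <- function(s, band = c(930, 980)) {
  stopifnot(inherits(s, "raman_spectrum"))
  win <- if (inherits(band, "band_definition")) band$window else
    as.numeric(band)
  idx <- which(as.numeric(s$axis) >= win[1] & as.numeric(s$axis) <= win[2])
  if (length(idx) == 0)
    stop("band window does not intersect the axis", call. = FALSE)
  peak <- max(s$intensities[idx])
  if (peak <= 0)
    stop("band maximum is not positive; cannot normalize", call. = FALSE)
  out <- raman_spectrum(s$axis, s$intensities / peak, s$meta)
  attr(out, "scale_factor") <- 1 / peak
  out
}
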