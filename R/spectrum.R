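#' Wavenumber axis
#'
#' A strictly increasing Raman-shift axis in cm^-1. The package's default
#' working axis spans the biological fingerprint region, 800-1800 cm^-1,
#' sampled at 499 evenly spaced points; files carrying other axes are
#' accepted anywhere a `wn_axis` is expected.
#'
#' @param values numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, length >= 8.
#' @return a numeric vector of class `wn_axis`.
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8L)
    stop("a wavenumber axis needs at least 8 points", call. = FALSE)
  if (any(!is.finite(values)))
    stop("wavenumber axis must be finite", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  structure(values, class = "wn_axis")
}

#' Default fingerprint-region axis: 800-1800 cm^-1, 499 points
#'
#' Covers the phosphate (~960), carbonate (~1070), Amide III (~1250),
#' CH2 (~1450) and Amide I (~1660 cm^-1) bands used throughout the
#' package.
#'
#' @return a `wn_axis` of length 499.
#' @export
default_axis <- function() {
  wavenumber_axis(seq(800, 1800, length.out = 499L))
}

#' Phalangeal position codes
#'
#' Measurement sites along a phalanx are coded relative to the anatomical
#' midpoint MM00: `MPxx` is xx mm proximal (negative mm), `MDxx` is xx mm
#' distal (positive mm). Codes are case-insensitive; zero renders as
#' `MM00`.
#'
#' @param code character vector of position codes (e.g. "MP05").
#' @return `position_to_mm`: signed millimetres (MP negative, MD
#'   positive); `mm_to_position`: the canonical code.
#' @examples
#' position_to_mm("MP05")  # -5
#' mm_to_position(15)      # "MD15"
#' @export
position_to_mm <- function(code) {
  code <- toupper(trimws(as.character(code)))
  out <- rep(NA_real_, length(code))
  ok <- grepl("^M[MPD][0-9]{2}$", code)
  if (any(!ok))
    stop("unknown position code(s): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  mm <- as.numeric(substr(code, 3L, 4L))
  dir <- substr(code, 2L, 2L)
  out[dir == "M"] <- 0
  out[dir == "P"] <- -mm[dir == "P"]
  out[dir == "D"] <- mm[dir == "D"]
  if (any(dir == "M" & mm != 0))
    stop("midpoint code must be MM00", call. = FALSE)
  out
}

#' @rdname position_to_mm
#' @param mm signed millimetres from the midpoint.
#' @export
mm_to_position <- function(mm) {
  mm <- as.numeric(mm)
  if (any(!is.finite(mm)) || any(mm != round(mm)) || any(abs(mm) > 99))
    stop("position must be an integer number of millimetres in [-99, 99]",
         call. = FALSE)
  ifelse(mm == 0, "MM00",
         sprintf("M%s%02d", ifelse(mm < 0, "P", "D"), abs(mm)))
}

#' Acquisition metadata for one Raman measurement
#'
#' @param subject_id opaque subject/cadaver identifier.
#' @param digit_phalanx site code such as "D2P1" (second digit, proximal
#'   phalanx).
#' @param position position code ("MP05") or signed millimetres (-5).
#' @param offset_mm lateral excitation-to-collection offset; one of 0, 3
#'   or 6 mm.
#' @param tissue `"transcutaneous"` or `"exposed_bone"`.
#' @return a list of class `acq_meta` with fields `subject_id`,
#'   `digit_phalanx`, `position_mm`, `position_code`, `offset_mm`,
#'   `tissue`.
#' @export
acquisition_meta <- function(subject_id, digit_phalanx = "D2P1",
                             position = 0, offset_mm = 6,
                             tissue = c("transcutaneous", "exposed_bone")) {
  tissue <- match.arg(tissue)
  if (is.character(position)) {
    position_mm <- position_to_mm(position)
  } else {
    position_mm <- as.numeric(position)
  }
  if (!offset_mm %in% c(0, 3, 6))
    stop("offset_mm must be one of 0, 3, 6", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 digit_phalanx = toupper(as.character(digit_phalanx)),
                 position_mm = position_mm,
                 position_code = mm_to_position(position_mm),
                 offset_mm = offset_mm,
                 tissue = tissue),
            class = "acq_meta")
}

#' A single Raman spectrum
#'
#' @param axis a `wn_axis` (or numeric vector coerced to one).
#' @param intensities numeric intensities (a.u.), same length as `axis`,
#'   all finite.
#' @param meta an `acq_meta`, or `NULL` for anonymous spectra.
#' @return a list of class `raman_spectrum` with fields `axis`,
#'   `intensities`, `meta`.
#' @export
raman_spectrum <- function(axis, intensities, meta = NULL) {
  if (!inherits(axis, "wn_axis")) axis <- wavenumber_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis))
    stop("intensities and axis lengths differ (",
         length(intensities), " vs ", length(axis), ")", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (!is.null(meta) && !inherits(meta, "acq_meta"))
    stop("meta must be an 'acq_meta' or NULL", call. = FALSE)
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(as.numeric(x$axis))
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1",
              length(x$axis), rng[1], rng[2]))
  if (!is.null(x$meta))
    cat(sprintf(" [%s %s %s, %g mm, %s]", x$meta$subject_id,
                x$meta$digit_phalanx, x$meta$position_code,
                x$meta$offset_mm, x$meta$tissue))
  cat("\n")
  invisible(x)
}

same_axis <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol)
}
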