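# Band-level biochemical metrics. Four ratios are computed against the
# phosphate band: PO4/CO3 (mineral quality, carbonate substitution) and
# three mineral-to-matrix ratios (PO4/Amide III, PO4/CH2, PO4/Amide I),
# plus the CH2 band width (FWHM) as an organic-matrix heterogeneity
# marker. Each band is quantified above a local linear baseline drawn
# through the window endpoints, either as peak height or integrated area.

#' Define a Raman band
#'
#' @param name band label; the metric set expects `PO4`, `CO3`,
#'   `AmideIII`, `CH2` and `AmideI`.
#' @param center nominal band center (cm^-1), strictly inside `window`.
#' @param window numeric `c(lo, hi)` integration window (cm^-1).
#' @param mode `"area"` (trapezoidal integral above the local baseline,
#'   default: more noise-robust) or `"height"` (baseline-corrected
#'   maximum).
#' @return a list of class `band_definition`.
#' @export
band_definition <- function(name, center, window,
                            mode = c("area", "height")) {
  mode <- match.arg(mode)
  window <- as.numeric(window)
  if (!(window[1] < center && center < window[2]))
    stop("band center must lie strictly inside its window", call. = FALSE)
  structure(list(name = name, center = center, window = window,
                 mode = mode), class = "band_definition")
}

#' Default band set for bone Raman spectra
#'
#' Standard assignments: phosphate nu1 960, carbonate nu1 1070, Amide III
#' 1250, CH2 deformation 1450, Amide I 1665 cm^-1, with windows wide
#' enough for the band shapes seen in cortical bone. All windows are
#' configurable; adjacent windows may not overlap by more than 10 cm^-1.
#'
#' @param mode quantification mode for all bands, `"area"` or `"height"`.
#' @return a named list of [band_definition()]s.
#' @export
default_bands <- function(mode = c("area", "height")) {
  mode <- match.arg(mode)
  defs <- list(
    PO4      = band_definition("PO4",      960, c(930, 980),  mode),
    CO3      = band_definition("CO3",     1070, c(1050, 1100), mode),
    AmideIII = band_definition("AmideIII", 1250, c(1215, 1300), mode),
    CH2      = band_definition("CH2",     1450, c(1400, 1500), mode),
    AmideI   = band_definition("AmideI",  1665, c(1595, 1720), mode))
  check_band_overlap(defs)
  defs
}

check_band_overlap <- function(bands) {
  nb <- length(bands)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i >= j) next
    ov <- min(bands[[i]]$window[2], bands[[j]]$window[2]) -
      max(bands[[i]]$window[1], bands[[j]]$window[1])
    if (ov > 10)
      stop("band windows '", bands[[i]]$name, "' and '", bands[[j]]$name,
           "' overlap by more than 10 cm^-1", call. = FALSE)
  }
  invisible(bands)
}

band_window_idx <- function(s, band) {
  x <- as.numeric(s$axis)
  idx <- which(x >= band$window[1] & x <= band$window[2])
  if (length(idx) < 3)
    stop("band window [", band$window[1], ", ", band$window[2],
         "] does not usefully intersect the axis", call. = FALSE)
  idx
}

# intensities above the straight line through the window's endpoint
# samples; removes constant/linear local background
local_corrected <- function(s, band) {
  idx <- band_window_idx(s, band)
  x <- as.numeric(s$axis)[idx]
  y <- s$intensities[idx]
  n <- length(idx)
  base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  list(x = x, y = y - base)
}

#' Quantify one band of a spectrum
#'
#' Height mode returns the maximum intensity in the window above a local
#' linear baseline through the window endpoints; area mode the
#' trapezoidal integral above the same baseline. Both are invariant to
#' adding a constant (or linear ramp) to the spectrum.
#'
#' @param s a [raman_spectrum()].
#' @param band a [band_definition()].
#' @return a single numeric band value (a.u., or a.u.*cm^-1 for area).
#' @export
band_value <- function(s, band) {
  stopifnot(inherits(band, "band_definition"))
  w <- local_corrected(s, band)
  if (band$mode == "height") max(w$y) else pracma::trapz(w$x, w$y)
}

#' Full width at half maximum of a band
#'
#' After local linear baseline removal, the band maximum inside the
#' window is located and the two half-maximum crossings are found by
#' linear interpolation between grid points.
#'
#' @inheritParams band_value
#' @return FWHM in cm^-1.
#' @export
fwhm <- function(s, band) {
  w <- local_corrected(s, band)
  i_max <- which.max(w$y)
  half <- w$y[i_max] / 2
  if (w$y[i_max] <= 0)
    stop("no peak above local baseline in window of band '", band$name,
         "'", call. = FALSE)
  cross <- function(i0, i1) {
    # linear interpolation between bracketing samples i0 (below) and i1
    w$x[i0] + (half - w$y[i0]) * (w$x[i1] - w$x[i0]) / (w$y[i1] - w$y[i0])
  }
  left <- NA_real_
  for (i in seq(i_max, 2L)) {
    if (w$y[i - 1] < half && w$y[i] >= half) { left <- cross(i - 1, i); break }
  }
  right <- NA_real_
  for (i in seq(i_max, length(w$y) - 1L)) {
    if (w$y[i + 1] < half && w$y[i] >= half) { right <- cross(i + 1, i); break }
  }
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found inside window of band '",
         band$name, "' (window too narrow)", call. = FALSE)
  right - left
}

#' Compute the Raman metric set for one spectrum
#'
#' @param s a [raman_spectrum()].
#' @param bands a named list of the five [band_definition()]s
#'   (`PO4`, `CO3`, `AmideIII`, `CH2`, `AmideI`).
#' @return a one-row data.frame: `po4_co3`, `po4_amideIII`, `po4_ch2`,
#'   `po4_amideI` (dimensionless ratios) and `ch2_fwhm` (cm^-1).
#' @export
compute_metrics <- function(s, bands = default_bands()) {
  need <- c("PO4", "CO3", "AmideIII", "CH2", "AmideI")
  miss <- setdiff(need, names(bands))
  if (length(miss) > 0)
    stop("missing band definition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- vapply(need, function(nm) band_value(s, bands[[nm]]), 0)
  for (nm in c("CO3", "AmideIII", "CH2", "AmideI"))
    if (v[nm] <= 0)
      stop("band '", nm, "' has non-positive value; ratio undefined",
           call. = FALSE)
  data.frame(po4_co3 = v["PO4"] / v["CO3"],
             po4_amideIII = v["PO4"] / v["AmideIII"],
             po4_ch2 = v["PO4"] / v["CH2"],
             po4_amideI = v["PO4"] / v["AmideI"],
             ch2_fwhm = fwhm(s, bands$CH2),
             row.names = NULL)
}

metric_names <- function() {
  c("po4_co3", "po4_amideIII", "po4_ch2", "po4_amideI", "ch2_fwhm")
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Group summaries of Raman metrics
#'
#' Aggregates to one value per subject first (mean over a subject's rows,
#' within position if `by_position`), then reports per-class mean, SD,
#' SEM = SD/sqrt(N) and N. A single-subject class reports SD = 0 (and
#' hence SEM = 0) by convention.
#'
#' @param metrics data.frame with a `subject_id` column, metric columns,
#'   and (if `by_position`) a `position_mm` column.
#' @param records data.frame with `subject_id` and `who_class`.
#' @param by_position also stratify by position along the phalanx.
#' @return a long data.frame: `who_class`, (`position_mm`), `metric`,
#'   `mean`, `sd`, `sem`, `n`.
#' @export
summarize_groups <- function(metrics, records, by_position = FALSE) {
  stopifnot("subject_id" %in% names(metrics))
  cls <- records$who_class[match(metrics$subject_id, records$subject_id)]
  if (any(is.na(cls)))
    stop("every subject in 'metrics' must appear in 'records'",
         call. = FALSE)
  metrics$who_class <- cls
  mcols <- intersect(metric_names(), names(metrics))
  if (length(mcols) == 0) mcols <- setdiff(
    names(metrics), c("subject_id", "who_class", "position_mm",
                      "position_code", "digit_phalanx"))
  keys <- if (by_position) c("who_class", "position_mm") else "who_class"
  subj_keys <- c("subject_id", if (by_position) "position_mm")
  agg1 <- stats::aggregate(metrics[mcols],
                           by = metrics[c(subj_keys, "who_class")],
                           FUN = mean)
  out <- list()
  for (m in mcols) {
    g <- stats::aggregate(
      agg1[[m]], by = agg1[keys],
      FUN = function(v) c(mean = mean(v), sd = sd0(v), n = length(v)))
    stat <- as.data.frame(g$x)
    out[[m]] <- data.frame(g[keys], metric = m, mean = stat$mean,
                           sd = stat$sd, sem = stat$sd / sqrt(stat$n),
                           n = as.integer(stat$n), row.names = NULL)
  }
  do.call(rbind, out) -> res
  rownames(res) <- NULL
  res
}

# Exact two-sided Mann-Whitney p-value by enumeration of group
# assignments, using mid-ranks so ties are handled (identical multisets
# give p = 1). Two-sided p = proportion of assignments whose U deviates
# from n1*n2/2 at least as much as the observed U.
mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks on ties
  u_from <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_from(seq_len(n1)) - n1 * n2 / 2)
  combos <- utils::combn(n1 + n2, n1)
  devs <- abs(apply(combos, 2, function(idx) sum(r[idx])) -
                n1 * (n1 + 1) / 2 - n1 * n2 / 2)
  mean(devs >= dev_obs - 1e-9)
}

#' Between-class significance test for a Raman metric
#'
#' One value per subject (rows aggregated by mean first), then a
#' two-sided test between the two named classes. The default is an exact
#' Mann-Whitney test computed by enumeration of all group assignments
#' with mid-ranks on ties (feasible at the cohort sizes used here, and
#' assumption-free at small n); a Welch t-test is available by flag. For
#' group sizes where enumeration exceeds `2e5` assignments the
#' normal-approximation Mann-Whitney is used instead.
#'
#' @inheritParams summarize_groups
#' @param pair character vector of two class labels, e.g.
#'   `c("Normal", "Osteoporosis")`.
#' @param metric metric column to test.
#' @param test `"mann_whitney"` (default) or `"welch"`.
#' @return the two-sided p-value.
#' @export
compare_classes <- function(metrics, records,
                            pair = c("Normal", "Osteoporosis"),
                            metric = "po4_amideIII",
                            test = c("mann_whitney", "welch")) {
  test <- match.arg(test)
  stopifnot(length(pair) == 2, metric %in% names(metrics))
  cls <- records$who_class[match(metrics$subject_id, records$subject_id)]
  metrics$who_class <- cls
  agg <- stats::aggregate(metrics[[metric]],
                          by = metrics[c("subject_id", "who_class")],
                          FUN = mean)
  x <- agg$x[agg$who_class == pair[1]]
  y <- agg$x[agg$who_class == pair[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("both classes need at least 2 subjects (got ", length(x), " and ",
         length(y), ")", call. = FALSE)
  if (test == "welch")
    return(stats::t.test(x, y)$p.value)
  if (choose(length(x) + length(y), length(x)) <= 2e5)
    mann_whitney_exact(x, y)
  else
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}
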