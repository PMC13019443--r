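# Synthetic paired-spectra cohorts with known ground truth.
#
# The generator emulates the structure of a cadaveric SORS study: each
# subject has a DXA T-score drawn from its WHO class's distribution
# (truncated to the class interval so labels stay consistent), an
# exposed-bone spectrum whose mineral bands scale with the T-score, and
# transcutaneous measurements that mix bone with overlying soft tissue,
# a fluorescence baseline and shot-like noise, with the bone fraction
# growing with lateral offset.

#' Configuration of the synthetic cohort generator
#'
#' Defaults: class T-score distributions Normal 0.05 +/- 0.45, Osteopenia
#' -1.63 +/- 0.38, Osteoporosis -4.19 +/- 0.90 (truncated to the WHO
#' interval of the class); bone peak table (center/sigma cm^-1,
#' amplitude a.u.) PO4 960/8/1.0, CO3 1070/10/0.35, Amide III
#' 1250/25/0.45, CH2 1450/15/0.80, Amide I 1665/30/0.90; mineral
#' amplitudes scale as exp(slope * T) with slope 0.10 for PO4 and 0.05
#' for CO3, so every mineral-to-matrix ratio and the PO4/CO3 ratio fall
#' monotonically from Normal to Osteoporosis; the CH2 width scales as
#' exp(-0.02 * T) so matrix heterogeneity rises toward osteoporosis.
#' Bone fractions by offset are 0.05 / 0.20 / 0.40 at 0 / 3 / 6 mm
#' (ordering, not magnitude, is the modelled physics: larger offsets
#' sample deeper). The fluorescence baseline is a gently decaying
#' polynomial several times the peak amplitudes, with a lognormal
#' per-measurement scale.
#'
#' @param axis working wavenumber axis.
#' @param class_tscore_params named list of `c(mean, sd)` per WHO class.
#' @param bone_peaks,soft_peaks data.frames with `name`, `center`,
#'   `sigma`, `amplitude`.
#' @param mineral_slopes named amplitude slopes for `PO4` and `CO3`.
#' @param ch2_sigma_slope width slope for the CH2 band.
#' @param bone_fraction_by_offset named fractions for offsets 0, 3, 6 mm;
#'   must lie in `[0, 1]` and be non-decreasing with offset.
#' @param baseline_coeffs polynomial coefficients (constant first) of the
#'   fluorescence baseline on the axis rescaled to `[0, 1]`.
#' @param baseline_jitter_sdlog lognormal sd of the per-measurement
#'   baseline scale.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param jitter_sdlog lognormal sd of per-subject/site peak-amplitude
#'   jitter.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(
    axis = default_axis(),
    class_tscore_params = list(Normal = c(0.05, 0.45),
                               Osteopenia = c(-1.63, 0.38),
                               Osteoporosis = c(-4.19, 0.90)),
    bone_peaks = data.frame(
      name = c("PO4", "CO3", "AmideIII", "CH2", "AmideI"),
      center = c(960, 1070, 1250, 1450, 1665),
      sigma = c(8, 10, 25, 15, 30),
      amplitude = c(1.00, 0.35, 0.45, 0.80, 0.90),
      stringsAsFactors = FALSE),
    soft_peaks = data.frame(
      name = c("lipid_CH2", "AmideI_soft", "lipid_twist", "collagen"),
      center = c(1450, 1660, 1300, 1250),
      sigma = c(18, 32, 20, 45),
      amplitude = c(1.20, 0.90, 0.50, 0.35),
      stringsAsFactors = FALSE),
    mineral_slopes = c(PO4 = 0.10, CO3 = 0.05),
    ch2_sigma_slope = 0.02,
    bone_fraction_by_offset = c("0" = 0.05, "3" = 0.20, "6" = 0.40),
    baseline_coeffs = c(3.0, -2.0, 0.5),
    baseline_jitter_sdlog = 0.2,
    noise_sd = 0.02,
    jitter_sdlog = 0.05) {
  stopifnot(all(bone_peaks$sigma > 0), all(bone_peaks$amplitude >= 0),
            all(soft_peaks$sigma > 0), noise_sd >= 0)
  f <- bone_fraction_by_offset[as.character(c(0, 3, 6))]
  if (any(is.na(f)) || any(f < 0 | f > 1) || any(diff(f) < 0))
    stop("bone fractions must be in [0,1] and non-decreasing with offset",
         call. = FALSE)
  structure(list(axis = axis, class_tscore_params = class_tscore_params,
                 bone_peaks = bone_peaks, soft_peaks = soft_peaks,
                 mineral_slopes = mineral_slopes,
                 ch2_sigma_slope = ch2_sigma_slope,
                 bone_fraction_by_offset = bone_fraction_by_offset,
                 baseline_coeffs = baseline_coeffs,
                 baseline_jitter_sdlog = baseline_jitter_sdlog,
                 noise_sd = noise_sd, jitter_sdlog = jitter_sdlog),
            class = "generator_config")
}

gaussian_sum <- function(axis, centers, sigmas, amplitudes) {
  x <- as.numeric(axis)
  y <- numeric(length(x))
  for (i in seq_along(centers))
    y <- y + amplitudes[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
  y
}

#' Generate a ground-truth exposed-bone spectrum
#'
#' A sum of Gaussian bands on the working axis. Mineral-band amplitudes
#' (PO4, CO3) scale as exp(slope * T-score), matrix bands stay fixed, so
#' all four metric ratios are monotone increasing in T-score; the CH2
#' width widens as the T-score falls. With `jitter = TRUE` each amplitude
#' is multiplied by a lognormal draw from the current RNG stream.
#'
#' @param tscore the subject's T-score (any real value).
#' @param cfg a [generator_config()].
#' @param jitter apply lognormal amplitude jitter.
#' @return a noiseless [raman_spectrum()].
#' @export
generate_bone_spectrum <- function(tscore, cfg = generator_config(),
                                   jitter = TRUE) {
  pk <- cfg$bone_peaks
  amp <- pk$amplitude
  for (nm in names(cfg$mineral_slopes)) {
    k <- which(pk$name == nm)
    amp[k] <- amp[k] * exp(cfg$mineral_slopes[[nm]] * tscore)
  }
  sig <- pk$sigma
  sig[pk$name == "CH2"] <- sig[pk$name == "CH2"] *
    exp(-cfg$ch2_sigma_slope * tscore)
  if (jitter)
    amp <- amp * stats::rlnorm(length(amp), 0, cfg$jitter_sdlog)
  raman_spectrum(cfg$axis, gaussian_sum(cfg$axis, pk$center, sig, amp))
}

#' Generate an overlying soft-tissue spectrum
#'
#' @inheritParams generate_bone_spectrum
#' @return a noiseless [raman_spectrum()] of skin/adipose/collagen bands.
#' @export
generate_soft_spectrum <- function(cfg = generator_config(),
                                   jitter = TRUE) {
  pk <- cfg$soft_peaks
  amp <- pk$amplitude
  if (jitter)
    amp <- amp * stats::rlnorm(length(amp), 0, cfg$jitter_sdlog)
  raman_spectrum(cfg$axis, gaussian_sum(cfg$axis, pk$center, pk$sigma, amp))
}

#' Mix bone and soft tissue into a transcutaneous measurement
#'
#' `f * bone + (1 - f) * soft + baseline + noise`, with the bone fraction
#' f looked up from the offset (larger offsets sample deeper, so f is
#' non-decreasing in offset).
#'
#' @param bone,soft [raman_spectrum()] objects on a shared axis.
#' @param offset_mm collection offset; must be a key of
#'   `cfg$bone_fraction_by_offset`.
#' @param cfg a [generator_config()].
#' @param baseline,noise disable the fluorescence baseline / additive
#'   noise (both draw from the current RNG stream when enabled).
#' @return a [raman_spectrum()].
#' @export
generate_transcutaneous <- function(bone, soft, offset_mm,
                                    cfg = generator_config(),
                                    baseline = TRUE, noise = TRUE) {
  if (!same_axis(bone$axis, soft$axis))
    stop("bone and soft spectra must share one axis", call. = FALSE)
  f <- cfg$bone_fraction_by_offset[as.character(offset_mm)]
  if (is.na(f))
    stop("no bone fraction configured for offset ", offset_mm, " mm",
         call. = FALSE)
  y <- f * bone$intensities + (1 - f) * soft$intensities
  if (baseline) {
    x <- as.numeric(bone$axis)
    u <- (x - x[1]) / (x[length(x)] - x[1])
    shape <- as.numeric(outer(u, seq_along(cfg$baseline_coeffs) - 1, `^`)
                        %*% cfg$baseline_coeffs)
    y <- y + shape * stats::rlnorm(1, 0, cfg$baseline_jitter_sdlog)
  }
  if (noise && cfg$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd)
  raman_spectrum(bone$axis, y)
}

# draw one T-score from the class distribution truncated to the class's
# WHO interval (rejection sampling)
sample_class_tscore <- function(who_class, cfg, rule = who_rule()) {
  p <- cfg$class_tscore_params[[who_class]]
  if (is.null(p)) stop("no T-score parameters for class ", who_class,
                       call. = FALSE)
  for (i in seq_len(10000)) {
    t <- stats::rnorm(1, p[1], p[2])
    if (as.character(classify_who(t, rule)) == who_class) return(t)
  }
  stop("truncated sampling failed for class ", who_class, call. = FALSE)
}

subject_substream <- function(seed, i) {
  # fan one global seed out to per-subject substreams so extending a
  # cohort never perturbs earlier subjects; kept below 2^31 - 1
  as.integer((as.numeric(seed) %% 65536 * 20011 + i * 104729) %%
               2147483629)
}

#' Generate a paired synthetic cohort with ground truth
#'
#' Per subject: a T-score drawn from its class distribution (truncated to
#' the WHO interval), sites MP05/MM00/MD05 on the D2P1 phalanx, a
#' noiseless ground-truth bone spectrum per site, the paired 3-mm
#' exposed-bone measurement (ground truth plus measurement noise) and the
#' 6-mm transcutaneous measurement (bone/soft mixture plus baseline and
#' noise). Each subject consumes its own RNG substream derived from
#' `seed`, so cohorts are reproducible and extensible.
#'
#' @param n_per_class subjects per class, in the order Normal,
#'   Osteopenia, Osteoporosis; default `c(6, 4, 11)` (a 21-donor cohort).
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return a list of class `sors_cohort`: `paired` (a
#'   [paired_dataset()]), `truth` (per-subject T-scores, classes,
#'   noiseless bone spectra and true MM00 metrics), `records`
#'   (data.frame `subject_id`, `tscore`, `who_class`).
#' @export
generate_cohort <- function(n_per_class = c(6, 4, 11),
                            cfg = generator_config(), seed = 1) {
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0))
  if (sum(n_per_class) == 0)
    stop("cohort is empty: all class counts are zero", call. = FALSE)
  classes <- rep(who_classes(), times = n_per_class)
  n <- length(classes)
  positions <- c(-5, 0, 5)
  Q <- length(cfg$axis)
  X <- matrix(NA_real_, n * length(positions), Q)
  Y <- matrix(NA_real_, n * length(positions), Q)
  subjects <- character(n * length(positions))
  site_pos <- numeric(n * length(positions))
  records <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                        tscore = NA_real_, who_class = classes,
                        stringsAsFactors = FALSE)
  truth_bone <- vector("list", n)
  truth_metrics <- vector("list", n)
  row <- 0L
  for (i in seq_len(n)) {
    set.seed(subject_substream(seed, i))
    tscore <- sample_class_tscore(classes[i], cfg)
    records$tscore[i] <- tscore
    soft <- generate_soft_spectrum(cfg)
    bones <- matrix(NA_real_, length(positions), Q,
                    dimnames = list(mm_to_position(positions), NULL))
    for (j in seq_along(positions)) {
      bone <- generate_bone_spectrum(tscore, cfg)
      bones[j, ] <- bone$intensities
      trans <- generate_transcutaneous(bone, soft, 6, cfg)
      ybone <- bone$intensities
      if (cfg$noise_sd > 0)
        ybone <- ybone + stats::rnorm(Q, 0, cfg$noise_sd)
      row <- row + 1L
      X[row, ] <- trans$intensities
      Y[row, ] <- ybone
      subjects[row] <- records$subject_id[i]
      site_pos[row] <- positions[j]
    }
    truth_bone[[i]] <- bones
    truth_metrics[[i]] <- compute_metrics(
      raman_spectrum(cfg$axis, bones["MM00", ]))
  }
  names(truth_bone) <- records$subject_id
  tm <- do.call(rbind, truth_metrics)
  tm <- cbind(data.frame(subject_id = records$subject_id,
                         stringsAsFactors = FALSE), tm)
  paired <- paired_dataset(
    cfg$axis, X, Y, subjects,
    sites = data.frame(digit_phalanx = "D2P1", position_mm = site_pos,
                       stringsAsFactors = FALSE))
  structure(list(paired = paired,
                 truth = list(tscores = stats::setNames(records$tscore,
                                                        records$subject_id),
                              who_class = stats::setNames(records$who_class,
                                                          records$subject_id),
                              bone = truth_bone, metrics = tm,
                              axis = cfg$axis),
                 records = records, seed = seed),
            class = "sors_cohort")
}

#' @export
print.sors_cohort <- function(x, ...) {
  tab <- table(factor(x$records$who_class, levels = who_classes()))
  cat(sprintf(paste0("<sors_cohort> %d subjects (%s), %d paired rows, ",
                     "seed %s\n"),
              nrow(x$records),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$paired$X), format(x$seed)))
  invisible(x)
}
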