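# Leave-one-subject-out reconstruction of exposed-bone spectra from
# transcutaneous SORS measurements, plus spectral-similarity scoring and
# class-averaged display spectra.

#' Pearson correlation between two spectra
#'
#' Computed across wavenumber points; invariant to affine intensity
#' transforms of either argument, so display normalization never changes
#' reported correlations.
#'
#' @param pred,ref [raman_spectrum()] objects on a shared axis, or plain
#'   numeric vectors of equal length.
#' @return the Pearson correlation coefficient.
#' @export
spectral_correlation <- function(pred, ref) {
  if (inherits(pred, "raman_spectrum") && inherits(ref, "raman_spectrum")) {
    if (!same_axis(pred$axis, ref$axis))
      stop("spectra must share one wavenumber axis", call. = FALSE)
    pred <- pred$intensities; ref <- ref$intensities
  }
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref))
    stop("spectra have different lengths", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0)
    stop("correlation undefined for a zero-variance spectrum",
         call. = FALSE)
  stats::cor(pred, ref)
}

#' Leave-one-subject-out bone-spectrum reconstruction
#'
#' For each subject in turn, a PLS2 model is trained on all other
#' subjects' (transcutaneous, exposed-bone) row pairs and used to predict
#' the held-out subject's bone spectra — so every prediction comes from a
#' model that never saw that subject. The number of latent components A
#' is fixed across folds (default 10).
#'
#' @param data a [paired_dataset()] (X = 6-mm transcutaneous, Y = 3-mm
#'   exposed bone).
#' @param A latent components per fold (default 10).
#' @param records optional data.frame (`subject_id`, `who_class`) to add
#'   per-class mean correlations.
#' @param algorithm passed to [fit_pls2()].
#' @return an object of class `reconstruction_result`: `predicted`
#'   (N x Q, input row order), `row_correlation`, `subject_correlation`
#'   (named), `class_correlation` (if `records` given), `A`, plus the
#'   dataset's `axis`, `subjects` and `sites`.
#' @export
loso_reconstruct <- function(data, A = 10, records = NULL,
                             algorithm = "simpls") {
  stopifnot(inherits(data, "paired_dataset"))
  subjects <- data$subjects
  us <- unique(subjects)
  if (length(us) < 3)
    stop("need at least 3 subjects for leave-one-subject-out",
         call. = FALSE)
  for (s in us) {
    n_tr <- sum(subjects != s)
    if (A > min(n_tr - 1, ncol(data$X)))
      stop("A = ", A, " infeasible when holding out subject ", s,
           " (", n_tr, " training rows)", call. = FALSE)
  }
  predicted <- matrix(NA_real_, nrow(data$Y), ncol(data$Y))
  for (s in us) {
    te <- subjects == s
    fit <- fit_pls2(data$X[!te, , drop = FALSE],
                    data$Y[!te, , drop = FALSE], A,
                    algorithm = algorithm)
    predicted[te, ] <- predict(fit, data$X[te, , drop = FALSE])
  }
  row_cor <- vapply(seq_len(nrow(predicted)), function(i)
    spectral_correlation(predicted[i, ], data$Y[i, ]), 0)
  subj_cor <- tapply(row_cor, subjects, mean)[us]
  class_cor <- NULL
  if (!is.null(records)) {
    cls <- records$who_class[match(us, records$subject_id)]
    class_cor <- tapply(as.numeric(subj_cor), cls, mean)
  }
  structure(list(predicted = predicted, row_correlation = row_cor,
                 subject_correlation = subj_cor,
                 class_correlation = class_cor, A = A,
                 axis = data$axis, subjects = subjects,
                 sites = data$sites),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(paste0("<reconstruction_result> %d rows, %d subjects, ",
                     "A = %d\n  mean held-out spectral correlation: ",
                     "%.4f\n"),
              nrow(x$predicted), length(unique(x$subjects)), x$A,
              mean(x$row_correlation)))
  if (!is.null(x$class_correlation)) {
    cc <- x$class_correlation
    cat("  per class:",
        paste(sprintf("%s %.4f", names(cc), cc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Class-averaged spectra
#'
#' Averages subject-first (one mean spectrum per subject, then one per
#' WHO class) so subjects with more sites do not dominate their class
#' mean. Optionally normalizes each class mean to a band maximum of one
#' (the usual phosphate-band display convention).
#'
#' @param spectra an N x Q matrix of spectra (e.g. `predicted` from
#'   [loso_reconstruct()]), or a `reconstruction_result`.
#' @param subjects subject id per row (taken from the result if omitted).
#' @param records data.frame with `subject_id` and `who_class` for every
#'   subject.
#' @param axis the shared wavenumber axis (taken from the result if
#'   omitted).
#' @param normalize `NULL` for raw means, or a band window /
#'   [band_definition()] passed to [normalize_to_band()].
#' @return a named list of [raman_spectrum()] class means; classes with
#'   no subjects are omitted with a warning.
#' @export
class_average_spectra <- function(spectra, records, subjects = NULL,
                                  axis = NULL, normalize = NULL) {
  if (inherits(spectra, "reconstruction_result")) {
    subjects <- subjects %||% spectra$subjects
    axis <- axis %||% spectra$axis
    spectra <- spectra$predicted
  }
  stopifnot(!is.null(subjects), !is.null(axis))
  spectra <- as.matrix(spectra)
  out <- list()
  for (cl in unique(records$who_class)) {
    subj_in <- records$subject_id[records$who_class == cl]
    subj_in <- intersect(subj_in, unique(subjects))
    if (length(subj_in) == 0) {
      warning("class '", cl, "' has no subjects; omitted")
      next
    }
    subj_means <- t(vapply(subj_in, function(s)
      colMeans(spectra[subjects == s, , drop = FALSE]),
      numeric(ncol(spectra))))
    m <- raman_spectrum(axis, colMeans(subj_means))
    if (!is.null(normalize)) m <- normalize_to_band(m, normalize)
    out[[cl]] <- m
  }
  out
}
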