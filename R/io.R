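# File readers/writers for spectra collections and site-matched pairing.
# Three plain-text dialects are supported: wide CSV (one row per spectrum),
# long CSV (one row per wavenumber) and JSON. Numeric values are written
# with 17 significant digits so doubles round-trip bit-identically.

meta_cols <- c("subject_id", "digit_phalanx", "position", "offset_mm",
               "tissue")

fmt17 <- function(x) sprintf("%.17g", x)

meta_to_row <- function(meta) {
  if (is.null(meta))
    return(data.frame(subject_id = NA_character_,
                      digit_phalanx = NA_character_,
                      position = NA_character_, offset_mm = NA_real_,
                      tissue = NA_character_, stringsAsFactors = FALSE))
  data.frame(subject_id = meta$subject_id,
             digit_phalanx = meta$digit_phalanx,
             position = meta$position_code, offset_mm = meta$offset_mm,
             tissue = meta$tissue, stringsAsFactors = FALSE)
}

row_to_meta <- function(row) {
  if (is.na(row$subject_id)) return(NULL)
  acquisition_meta(subject_id = row$subject_id,
                   digit_phalanx = row$digit_phalanx,
                   position = row$position,
                   offset_mm = as.numeric(row$offset_mm),
                   tissue = row$tissue)
}

#' Read a collection of spectra from file
#'
#' All spectra in one file must share a single wavenumber axis; a spectrum
#' with a deviating number of points is a format error. Acquisition
#' metadata (subject, digit/phalanx, position code, offset, tissue) is
#' parsed from the metadata columns when present.
#'
#' @param path file to read.
#' @param dialect `"wide_csv"` (one row per spectrum, wavenumber columns
#'   prefixed `wn_`), `"long_csv"` (columns `spectrum`, metadata,
#'   `wavenumber`, `intensity`), or `"json"`.
#' @return a list of [raman_spectrum()] objects sharing one axis, in file
#'   order.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "long_csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
         wide_csv = read_spectra_wide(path),
         long_csv = read_spectra_long(path),
         json = read_spectra_json(path))
}

read_spectra_wide <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        stringsAsFactors = FALSE)
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (length(wn_cols) == 0)
    stop("wide CSV has no wn_* wavenumber columns", call. = FALSE)
  axis <- wavenumber_axis(as.numeric(sub("^wn_", "", wn_cols)))
  lapply(seq_len(nrow(df)), function(i) {
    raman_spectrum(axis, as.numeric(df[i, wn_cols]),
                   row_to_meta(df[i, , drop = FALSE]))
  })
}

read_spectra_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spectrum", "wavenumber", "intensity")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- unique(df$spectrum)
  first <- df[df$spectrum == ids[1], ]
  axis <- wavenumber_axis(first$wavenumber)
  lapply(ids, function(id) {
    sub <- df[df$spectrum == id, ]
    if (nrow(sub) != length(axis) ||
        !same_axis(axis, wavenumber_axis(sub$wavenumber)))
      stop("spectrum ", id, " does not share the file's wavenumber axis",
           call. = FALSE)
    raman_spectrum(axis, sub$intensity, row_to_meta(sub[1, , drop = FALSE]))
  })
}

read_spectra_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  axis <- wavenumber_axis(as.numeric(obj$axis))
  lapply(obj$spectra, function(rec) {
    y <- as.numeric(rec$intensities)
    if (length(y) != length(axis))
      stop("spectrum '", rec$subject_id %||% "?",
           "' has ", length(y), " points; axis has ", length(axis),
           call. = FALSE)
    meta <- if (is.null(rec$subject_id)) NULL else
      acquisition_meta(rec$subject_id, rec$digit_phalanx, rec$position,
                       as.numeric(rec$offset_mm), rec$tissue)
    raman_spectrum(axis, y, meta)
  })
}

#' Write a collection of spectra to file
#'
#' @param spectra a list of [raman_spectrum()] objects sharing one axis.
#' @inheritParams read_spectra
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path,
                          dialect = c("wide_csv", "long_csv", "json")) {
  dialect <- match.arg(dialect)
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  axis <- spectra[[1]]$axis
  for (s in spectra)
    if (!same_axis(axis, s$axis))
      stop("all spectra must share one axis to be written together",
           call. = FALSE)
  switch(dialect,
         wide_csv = write_spectra_wide(spectra, axis, path),
         long_csv = write_spectra_long(spectra, axis, path),
         json = write_spectra_json(spectra, axis, path))
  invisible(path)
}

write_spectra_wide <- function(spectra, axis, path) {
  meta <- do.call(rbind, lapply(spectra, function(s) meta_to_row(s$meta)))
  mat <- do.call(rbind, lapply(spectra, function(s) fmt17(s$intensities)))
  colnames(mat) <- paste0("wn_", fmt17(as.numeric(axis)))
  utils::write.csv(cbind(meta, as.data.frame(mat, stringsAsFactors = FALSE)),
                   path, row.names = FALSE, quote = FALSE, na = "")
}

write_spectra_long <- function(spectra, axis, path) {
  rows <- lapply(seq_along(spectra), function(i) {
    m <- meta_to_row(spectra[[i]]$meta)
    data.frame(spectrum = i, m,
               wavenumber = fmt17(as.numeric(axis)),
               intensity = fmt17(spectra[[i]]$intensities),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
}

write_spectra_json <- function(spectra, axis, path) {
  obj <- list(axis = as.numeric(axis),
              spectra = lapply(spectra, function(s) {
                m <- meta_to_row(s$meta)
                rec <- if (is.na(m$subject_id)) list() else
                  list(subject_id = m$subject_id,
                       digit_phalanx = m$digit_phalanx,
                       position = m$position, offset_mm = m$offset_mm,
                       tissue = m$tissue)
                c(rec, list(intensities = s$intensities))
              }))
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired predictor/response dataset
#'
#' Row-aligned matrices of transcutaneous (X, 6-mm offset) and
#' exposed-bone (Y, 3-mm offset) spectra with subject grouping for
#' leakage-safe cross-validation. Usually built by [pair_by_site()] or
#' [generate_cohort()].
#'
#' @param axis shared `wn_axis`.
#' @param X,Y numeric matrices, N x P and N x Q, row-aligned by
#'   (subject, site).
#' @param subjects character N-vector of subject ids.
#' @param sites data.frame with columns `digit_phalanx`, `position_mm`.
#' @param unmatched optional data.frame describing spectra that found no
#'   partner during pairing.
#' @return a list of class `paired_dataset`.
#' @export
paired_dataset <- function(axis, X, Y, subjects, sites, unmatched = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) == length(subjects),
            nrow(X) == nrow(sites), ncol(X) == length(axis),
            ncol(Y) == length(axis))
  sites$position_code <- mm_to_position(sites$position_mm)
  structure(list(axis = axis, X = X, Y = Y,
                 subjects = as.character(subjects), sites = sites,
                 unmatched = unmatched),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(paste0("<paired_dataset> %d rows (%d subjects), ",
                     "%d wavenumber points\n"),
              nrow(x$X), length(unique(x$subjects)), ncol(x$X)))
  if (!is.null(x$unmatched) && nrow(x$unmatched) > 0)
    cat(sprintf("  %d unmatched spectra reported\n", nrow(x$unmatched)))
  invisible(x)
}

#' Pair transcutaneous and exposed-bone spectra by site
#'
#' Rows are formed only where a (subject, digit/phalanx, position) key is
#' present in both collections and the position lies inside the modelling
#' window (default MP05-MD05, the stable mid-phalangeal region). Rows are
#' sorted canonically by (subject, digit/phalanx, position) so pairing is
#' invariant to input ordering; unmatched spectra are reported in the
#' result.
#'
#' @param trans transcutaneous spectra (all at 6-mm offset).
#' @param bone exposed-bone spectra (all at 3-mm offset).
#' @param window numeric `c(lo, hi)` position window in signed mm.
#' @return a [paired_dataset()].
#' @export
pair_by_site <- function(trans, bone, window = c(-5, 5)) {
  stopifnot(length(trans) > 0, length(bone) > 0)
  axis <- trans[[1]]$axis
  for (s in c(trans, bone))
    if (!same_axis(axis, s$axis))
      stop("all spectra must share one wavenumber axis", call. = FALSE)
  key_of <- function(s) {
    m <- s$meta
    if (is.null(m)) stop("pairing requires acquisition metadata",
                         call. = FALSE)
    paste(m$subject_id, m$digit_phalanx, m$position_mm, sep = "\r")
  }
  off <- function(lst) vapply(lst, function(s) s$meta$offset_mm, 0)
  tk <- vapply(trans, key_of, ""); bk <- vapply(bone, key_of, "")
  if (any(off(trans) != 6))
    stop("transcutaneous spectra must all be at 6-mm offset", call. = FALSE)
  if (any(off(bone) != 3))
    stop("exposed-bone spectra must all be at 3-mm offset", call. = FALSE)
  pos_of <- function(lst) vapply(lst, function(s) s$meta$position_mm, 0)
  in_win <- function(p) p >= window[1] & p <= window[2]
  keep_t <- in_win(pos_of(trans)); keep_b <- in_win(pos_of(bone))
  common <- intersect(tk[keep_t], bk[keep_b])
  if (length(common) == 0)
    stop("no (subject, site) keys shared by both collections inside the ",
         "window", call. = FALSE)
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  ord <- order(parts[, 1], parts[, 2], as.numeric(parts[, 3]))
  common <- common[ord]; parts <- parts[ord, , drop = FALSE]
  ti <- match(common, tk); bi <- match(common, bk)
  X <- do.call(rbind, lapply(trans[ti], function(s) s$intensities))
  Y <- do.call(rbind, lapply(bone[bi], function(s) s$intensities))
  miss_df <- function(side, keys) {
    data.frame(side = rep(side, length(keys)),
               key = gsub("\r", "/", keys, fixed = TRUE),
               stringsAsFactors = FALSE)
  }
  um <- rbind(miss_df("transcutaneous", setdiff(tk, common)),
              miss_df("exposed_bone", setdiff(bk, common)))
  paired_dataset(axis, X, Y, subjects = parts[, 1],
                 sites = data.frame(digit_phalanx = parts[, 2],
                                    position_mm = as.numeric(parts[, 3]),
                                    stringsAsFactors = FALSE),
                 unmatched = um)
}
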