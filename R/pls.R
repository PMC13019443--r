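# Multi-response partial least squares (PLS2), written from scratch.
#
# The reference algorithm is SIMPLS (de Jong 1993): latent components are
# extracted from the cross-product S = Xc' Yc as its dominant singular
# pair, with S deflated against an orthonormal basis of X-loadings so
# successive X-scores are mutually orthogonal. X and Y are mean-centered
# only (no unit-variance scaling); the model carries an explicit
# intercept. A NIPALS variant is provided behind a flag.
#
# The dominant singular pair of S = Xd' Yc is computed exactly via thin
# QR of Xd' and Yc' and an SVD of the small core, so the cost per
# component is O(N^2 (P + Q)) rather than O(P Q min(P, Q)) — this keeps
# 499-channel leave-one-subject-out loops fast without approximation.

# exact dominant singular pair of t(Xd) %*% Y0 without forming it
dominant_pair <- function(Xd, Y0) {
  qa <- qr(t(Xd))
  qb <- qr(t(Y0))
  M <- qr.R(qa) %*% t(qr.R(qb))   # small core, k1 x k2 with k <= N
  sv <- svd(M, nu = 1, nv = 1)
  r <- as.numeric(qr.Q(qa) %*% sv$u[, 1])
  # canonical sign: largest-magnitude weight positive (determinism)
  if (r[which.max(abs(r))] < 0) r <- -r
  list(r = r, d = sv$d[1])
}

#' Fit a multi-response PLS (PLS2) regression
#'
#' Learns a linear map from predictor spectra X (N x P) to response
#' spectra Y (N x Q) through A latent components chosen to maximize
#' X-Y score covariance under orthogonality constraints. Predictions use
#' the augmented coefficient matrix: `Yhat = [1 | X] %*% B_tilde`, where
#' `B_tilde` stacks the intercept `b0 = y_mean - x_mean' B` on top of the
#' P x Q coefficient matrix B.
#'
#' Columns of X with zero variance carry no information after centering;
#' they are dropped with a warning and re-inserted as zero coefficient
#' rows (never silent NaN). Deflation directions with negligible norm
#' terminate extraction early with a warning, capping A.
#'
#' @param X numeric N x P predictor matrix.
#' @param Y numeric N x Q response matrix (a vector is treated as Q = 1).
#' @param A number of latent components, `1 <= A <= min(N-1, P)`.
#' @param algorithm `"simpls"` (reference) or `"nipals"`.
#' @return an object of class `pls_model` with elements `A` (effective
#'   number of components), `x_mean`, `y_mean`, `weights` (P x A),
#'   `x_loadings` (P x A), `y_loadings` (Q x A), `scores` (N x A,
#'   orthogonal columns), `coefficients` (P x Q), `b0` (Q), `B_tilde`
#'   ((P+1) x Q) and `algorithm`.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to
#'   partial least squares regression. Chemometrics Intell. Lab. Syst.
#'   18, 251-263.
#' @export
fit_pls2 <- function(X, Y, A, algorithm = c("simpls", "nipals")) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  N <- nrow(X); P <- ncol(X); Q <- ncol(Y)
  if (N < 2) stop("need at least 2 training rows", call. = FALSE)
  if (nrow(Y) != N) stop("X and Y row counts differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("X and Y must be finite", call. = FALSE)
  if (A < 1 || A > min(N - 1, P))
    stop("A must satisfy 1 <= A <= min(N-1, P) = ", min(N - 1, P),
         call. = FALSE)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean); Yc <- sweep(Y, 2, y_mean)
  colvar <- colSums(Xc^2)
  kept <- which(colvar > 1e-24 * max(1, max(colvar)))
  if (length(kept) == 0)
    stop("X has zero variance in every column; nothing to fit",
         call. = FALSE)
  if (length(kept) < P)
    warning(P - length(kept),
            " zero-variance X column(s) dropped from the fit ",
            "(zero coefficients reported)")
  Xk <- Xc[, kept, drop = FALSE]
  Pk <- length(kept)
  A <- min(A, Pk)
  core <- if (algorithm == "simpls") simpls_core(Xk, Yc, A)
          else nipals_core(Xk, Yc, A)
  expand <- function(M) {
    full <- matrix(0, P, ncol(M))
    full[kept, ] <- M
    full
  }
  B <- expand(core$B)
  b0 <- as.numeric(y_mean - crossprod(B, x_mean))
  B_tilde <- rbind(b0, B)
  dimnames(B_tilde) <- NULL
  model <- structure(list(
    A = core$A, algorithm = algorithm,
    x_mean = x_mean, y_mean = y_mean,
    weights = expand(core$W), x_loadings = expand(core$Pl),
    y_loadings = core$Ql, scores = core$Tm,
    coefficients = B, b0 = b0,
    B_tilde = B_tilde,
    kept_columns = kept), class = "pls_model")
  model
}

simpls_core <- function(X0, Y0, A) {
  N <- nrow(X0); P <- ncol(X0); Q <- ncol(Y0)
  W <- matrix(0, P, A); Pl <- matrix(0, P, A); Ql <- matrix(0, Q, A)
  Tm <- matrix(0, N, A); V <- matrix(0, P, A)
  Xd <- X0
  d1 <- NULL
  a_eff <- 0L
  for (a in seq_len(A)) {
    dp <- dominant_pair(Xd, Y0)
    if (is.null(d1)) d1 <- dp$d
    if (dp$d < 1e-12 * max(1, d1)) {
      warning("deflated cross-product is numerically zero; stopping at ",
              a_eff, " component(s)")
      break
    }
    r <- dp$r
    t_ <- as.numeric(X0 %*% r)
    normt <- sqrt(sum(t_^2))
    if (normt < 1e-12) {
      warning("degenerate score vector; stopping at ", a_eff,
              " component(s)")
      break
    }
    t_ <- t_ / normt; r <- r / normt
    p_ <- as.numeric(crossprod(X0, t_))
    q_ <- as.numeric(crossprod(Y0, t_))
    v <- p_
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- as.numeric(v) / sqrt(sum(v^2))
    Xd <- Xd - (Xd %*% v) %*% t(v)
    W[, a] <- r; Pl[, a] <- p_; Ql[, a] <- q_; Tm[, a] <- t_; V[, a] <- v
    a_eff <- a
  }
  if (a_eff == 0L) stop("no PLS component could be extracted", call. = FALSE)
  idx <- seq_len(a_eff)
  W <- W[, idx, drop = FALSE]; Pl <- Pl[, idx, drop = FALSE]
  Ql <- Ql[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  list(A = a_eff, W = W, Pl = Pl, Ql = Ql, Tm = Tm,
       B = W %*% t(Ql))
}

nipals_core <- function(X0, Y0, A, tol = 1e-12, max_iter = 500L) {
  N <- nrow(X0); P <- ncol(X0); Q <- ncol(Y0)
  W <- matrix(0, P, A); Pl <- matrix(0, P, A); Ql <- matrix(0, Q, A)
  Tm <- matrix(0, N, A)
  Xd <- X0; Yd <- Y0
  a_eff <- 0L
  for (a in seq_len(A)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    if (sum(u^2) < 1e-24) {
      warning("response residual exhausted; stopping at ", a_eff,
              " component(s)")
      break
    }
    t_old <- rep(Inf, N)
    for (it in seq_len(max_iter)) {
      w <- as.numeric(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-15) break
      w <- w / nw
      t_ <- as.numeric(Xd %*% w)
      q_ <- as.numeric(crossprod(Yd, t_)) / sum(t_^2)
      u <- as.numeric(Yd %*% q_) / sum(q_^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    if (sqrt(sum(w^2)) < 1e-15 || sum(t_^2) < 1e-24) {
      warning("degenerate NIPALS direction; stopping at ", a_eff,
              " component(s)")
      break
    }
    p_ <- as.numeric(crossprod(Xd, t_)) / sum(t_^2)
    q_ <- as.numeric(crossprod(Yd, t_)) / sum(t_^2)
    Xd <- Xd - tcrossprod(t_, p_)
    Yd <- Yd - tcrossprod(t_, q_)
    W[, a] <- w; Pl[, a] <- p_; Ql[, a] <- q_; Tm[, a] <- t_
    a_eff <- a
  }
  if (a_eff == 0L) stop("no PLS component could be extracted", call. = FALSE)
  idx <- seq_len(a_eff)
  W <- W[, idx, drop = FALSE]; Pl <- Pl[, idx, drop = FALSE]
  Ql <- Ql[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
  # B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(Pl, W), t(Ql))
  list(A = a_eff, W = W, Pl = Pl, Ql = Ql, Tm = Tm, B = B)
}

#' Predict responses from a fitted PLS model
#'
#' @param object a `pls_model` from [fit_pls2()].
#' @param newdata numeric M x P matrix (or P-vector for one row).
#' @param ... unused.
#' @return an M x Q matrix: `[1 | newdata] %*% B_tilde`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$x_mean), call. = FALSE)
  cbind(1, X) %*% object$B_tilde
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s, A = %d components, P = %d -> Q = %d\n",
              x$algorithm, x$A, length(x$x_mean), length(x$y_mean)))
  invisible(x)
}

# coefficients truncated to the first `a` components (SIMPLS/NIPALS
# components are nested, so rank-a predictions come from prefix sums)
coef_at_rank <- function(model, a) {
  stopifnot(a >= 1, a <= model$A)
  if (model$algorithm == "nipals") {
    W <- model$weights[, seq_len(a), drop = FALSE]
    Pl <- model$x_loadings[, seq_len(a), drop = FALSE]
    Ql <- model$y_loadings[, seq_len(a), drop = FALSE]
    B <- W %*% solve(crossprod(Pl, W), t(Ql))
  } else {
    B <- model$weights[, seq_len(a), drop = FALSE] %*%
      t(model$y_loadings[, seq_len(a), drop = FALSE])
  }
  b0 <- as.numeric(model$y_mean - crossprod(B, model$x_mean))
  list(B = B, b0 = b0)
}

predict_at_rank <- function(model, newdata, a) {
  cb <- coef_at_rank(model, a)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  sweep(X %*% cb$B, 2, cb$b0, `+`)
}

#' Choose the number of latent components by grouped K-fold CV
#'
#' Folds are defined on subject identity so no subject is split between
#' training and test (leakage-safe for repeated within-subject
#' measurements). Subjects are assigned to folds round-robin in order of
#' first appearance, so the selection is deterministic. The error for
#' each candidate rank is the root mean squared prediction error pooled
#' over all held-out rows and response channels; ties break to the
#' smallest rank (parsimony).
#'
#' @param X,Y training matrices as in [fit_pls2()].
#' @param groups subject label for each row.
#' @param ranks candidate component counts (duplicates are evaluated
#'   once).
#' @param k_folds number of folds (default 5); must not exceed the number
#'   of distinct subjects.
#' @return an object of class `component_selection`: `ranks`, `cv_rmse`,
#'   `chosen`.
#' @export
select_components <- function(X, Y, groups, ranks = 1:10, k_folds = 5) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X))
  ug <- unique(groups)
  if (length(ug) < k_folds)
    stop("fewer distinct subjects (", length(ug), ") than folds (",
         k_folds, ")", call. = FALSE)
  ranks <- sort(unique(as.integer(ranks)))
  if (any(ranks < 1)) stop("ranks must be >= 1", call. = FALSE)
  fold_of <- stats::setNames(((seq_along(ug) - 1L) %% k_folds) + 1L, ug)
  row_fold <- fold_of[groups]
  a_max <- max(ranks)
  for (f in seq_len(k_folds)) {
    n_tr <- sum(row_fold != f)
    if (a_max > min(n_tr - 1, ncol(X)))
      stop("rank ", a_max, " infeasible for fold ", f, " (",
           n_tr, " training rows)", call. = FALSE)
  }
  sse <- stats::setNames(numeric(length(ranks)), ranks)
  for (f in seq_len(k_folds)) {
    tr <- row_fold != f
    fit <- fit_pls2(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], a_max)
    for (i in seq_along(ranks)) {
      a <- min(ranks[i], fit$A)
      pred <- predict_at_rank(fit, X[!tr, , drop = FALSE], a)
      sse[i] <- sse[i] + sum((pred - Y[!tr, , drop = FALSE])^2)
    }
  }
  cv_rmse <- sqrt(sse / (nrow(X) * ncol(Y)))
  chosen <- ranks[which.min(cv_rmse)]  # which.min takes first == smallest
  structure(list(ranks = ranks, cv_rmse = unname(cv_rmse),
                 chosen = chosen, k_folds = k_folds, folds = fold_of),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> chosen A = %d (grouped %d-fold CV)\n",
              x$chosen, x$k_folds))
  print(data.frame(rank = x$ranks, cv_rmse = signif(x$cv_rmse, 5)))
  invisible(x)
}

#' Serialize / restore a PLS model as JSON
#'
#' @param model a `pls_model`.
#' @param path file to write / read.
#' @return `save_pls_model`: `path` invisibly; `load_pls_model`: the
#'   restored `pls_model`.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- unclass(model)
  obj$scores <- NULL  # training scores are not needed for prediction
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pls_model
#' @export
load_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    unname(m)
  }
  for (f in c("weights", "x_loadings", "y_loadings", "coefficients",
              "B_tilde"))
    obj[[f]] <- num_mat(obj[[f]])
  structure(obj, class = "pls_model")
}
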