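#' Fit a PLS1 calibration (NIPALS)
#'
#' Single-response partial least squares regression by the NIPALS algorithm
#' with X-deflation.  X and y are mean-centered internally (no autoscaling,
#' the standard choice for spectra; set `autoscale = TRUE` to scale X columns
#' to unit variance).  Deterministic for fixed input order.
#'
#' @param X numeric matrix (n x p) of pretreated spectra.
#' @param y numeric response vector (%DM), length n.
#' @param rank number of latent components ("ranks"), `1 <= rank <= min(n-1, p)`.
#' @param autoscale scale X columns to unit sd (default FALSE).
#' @param strict error when the X'y residual vanishes before `rank`
#'   components (exactly collinear / noiseless systems); with
#'   `strict = FALSE` the factorization truncates at the last informative
#'   component and `$rank` reports the achieved rank.
#' @return A `pls_fit`: list with centering vectors, weight/loading matrices
#'   `W`, `P`, y-loadings `q`, regression coefficients `coef` (p-vector) and
#'   `intercept`, and per-rank coefficient access via [pls_coef].
#' @export
fit_pls1 <- function(X, y, rank, autoscale = FALSE, strict = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (stats::var(y) == 0) stop("response has zero variance")
  if (rank < 1 || rank > min(n - 1, p))
    stop("rank must be in [1, ", min(n - 1, p), "]")
  x_mean <- colMeans(X)
  x_scale <- if (autoscale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) x_scale[x_scale == 0] <- 1
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean
  W <- matrix(0, p, rank)
  P <- matrix(0, p, rank)
  Tm <- matrix(0, n, rank)
  q <- numeric(rank)
  Xd <- Xc; yd <- yc
  for (a in seq_len(rank)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      if (strict)
        stop("X'y residual vanished at component ", a,
             "; reduce rank (max informative rank reached)")
      rank <- a - 1L
      W <- W[, seq_len(rank), drop = FALSE]
      P <- P[, seq_len(rank), drop = FALSE]
      Tm <- Tm[, seq_len(rank), drop = FALSE]
      q <- q[seq_len(rank)]
      break
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t)[, 1] / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t[, 1]
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  if (rank == 0) stop("response is orthogonal to the predictors")
  # coefficients in centered-X space: B = W (P'W)^-1 q
  B <- W %*% solve(t(P) %*% W, q)
  coef <- B[, 1] / x_scale
  structure(list(x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 W = W, P = P, q = q, scores = Tm, rank = rank,
                 coef = coef, intercept = y_mean - sum(x_mean * coef),
                 fitted = as.numeric(y_mean + sweep(X, 2, x_mean) %*% coef)),
            class = "pls_fit")
}

#' Regression coefficients of a PLS1 fit at a given rank
#'
#' @param fit a `pls_fit`.
#' @param rank number of components to use (default: the fitted rank).
#' @return list with `coef` (p-vector, original X units) and `intercept`.
#' @export
pls_coef <- function(fit, rank = fit$rank) {
  stopifnot(inherits(fit, "pls_fit"), rank >= 1, rank <= fit$rank)
  W <- fit$W[, seq_len(rank), drop = FALSE]
  P <- fit$P[, seq_len(rank), drop = FALSE]
  q <- fit$q[seq_len(rank)]
  B <- W %*% solve(t(P) %*% W, q)
  coef <- B[, 1] / fit$x_scale
  list(coef = coef, intercept = fit$y_mean - sum(fit$x_mean * coef))
}

#' @export
predict.pls_fit <- function(object, newdata, rank = object$rank, ...) {
  cf <- pls_coef(object, rank)
  as.numeric(cf$intercept + as.matrix(newdata) %*% cf$coef)
}

#' Cross-validated rank selection for PLS1
#'
#' For each rank `1..max_rank`, computes the root mean square error of
#' cross-validation (RMSECV) over held-out predictions under a deterministic
#' scheme: leave-one-out (default) or contiguous-block k-fold in the given
#' sample order.  The chosen rank minimizes RMSECV, ties going to the
#' smaller rank.
#'
#' @param X numeric matrix (n x p).
#' @param y response vector.
#' @param max_rank largest rank to try; must leave every training fold with
#'   at least `max_rank + 1` samples.
#' @param scheme `"LOO"` or `"kfold"`.
#' @param k number of folds for `"kfold"` (default 10).
#' @return A `cv_result`: list with `rmsecv` (length `max_rank`), `rank`
#'   (chosen), `predictions` (cross-validated predictions at the chosen
#'   rank) and `press` per rank.
#' @export
cross_validate <- function(X, y, max_rank, scheme = c("LOO", "kfold"), k = 10) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- if (scheme == "LOO") as.list(seq_len(n)) else {
    k <- min(k, n)
    split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
  }
  min_train <- n - max(lengths(folds))
  if (max_rank >= min_train)
    stop("max_rank (", max_rank, ") must be < smallest training-fold size (",
         min_train, ")")
  pred <- matrix(NA_real_, n, max_rank)
  for (fold in folds) {
    fit <- fit_pls1(X[-fold, , drop = FALSE], y[-fold], max_rank,
                    strict = FALSE)
    for (a in seq_len(max_rank))
      pred[fold, a] <- predict(fit, X[fold, , drop = FALSE],
                               rank = min(a, fit$rank))
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  chosen <- which.min(rmsecv)  # first minimum = smallest rank on ties
  structure(list(rmsecv = rmsecv, rank = chosen,
                 predictions = pred[, chosen],
                 press = colSums((pred - y)^2)),
            class = "cv_result")
}

#' Grid search over pretreatment candidates
#'
#' Runs pretreatment + cross-validation for each candidate
#' [pretreatment_spec] and ranks candidates by their best (rank-optimized)
#' RMSECV, ascending.  A candidate that fails (e.g. a degenerate spectrum
#' under its transform) is recorded as failed, not fatal.
#'
#' @param s calibration [spectra_set] (full grid).
#' @param y response vector aligned with `s$sample_ids`.
#' @param candidates list of [pretreatment_spec] objects.
#' @param max_rank maximum PLS rank to cross-validate.
#' @param scheme,k passed to [cross_validate].
#' @return A data.frame (one row per candidate, sorted by RMSECV) with the
#'   candidate label, chosen rank, best RMSECV and an `ok` flag; the full
#'   `cv_result` objects and specs are attached as attributes `cv` and
#'   `specs` (in sorted order).
#' @export
grid_search <- function(s, y, candidates, max_rank,
                        scheme = c("LOO", "kfold"), k = 10) {
  scheme <- match.arg(scheme)
  if (length(candidates) == 0) stop("candidate list is empty")
  labels <- vapply(candidates, function(sp)
    if (length(sp$steps)) paste(sp$steps, collapse = "+") else "raw", "")
  res <- lapply(candidates, function(sp) {
    tryCatch({
      pre <- apply_pretreatment(s, sp)
      cv <- cross_validate(pre$spectra$absorbance, y, max_rank, scheme, k)
      list(ok = TRUE, cv = cv, err = NA_character_)
    }, error = function(e)
      list(ok = FALSE, cv = NULL, err = conditionMessage(e)))
  })
  best <- vapply(res, function(r)
    if (r$ok) min(r$cv$rmsecv) else Inf, 0)
  ord <- order(best, seq_along(best))
  tab <- data.frame(
    pretreatment = labels[ord],
    rank = vapply(res[ord], function(r) if (r$ok) r$cv$rank else NA_integer_, 0L),
    rmsecv = ifelse(is.finite(best[ord]), best[ord], NA_real_),
    ok = vapply(res[ord], `[[`, TRUE, "ok"),
    error = vapply(res[ord], `[[`, "", "err"),
    stringsAsFactors = FALSE)
  attr(tab, "cv") <- lapply(res[ord], `[[`, "cv")
  attr(tab, "specs") <- candidates[ord]
  tab
}
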