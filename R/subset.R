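#' Kennard-Stone representative sample selection
#'
#' Deterministic greedy max-min selection in Euclidean distance on the
#' column-mean-centered absorbance matrix.  The first two selections are the
#' most distant pair of samples; each subsequent selection maximizes its
#' minimum distance to the already-selected set.  Ties are broken by smallest
#' row index, and within the seed pair by row order, so the output is a
#' deterministic ordered list and the first k selections of
#' `kennard_stone(s, k + 1)` equal `kennard_stone(s, k)`.
#'
#' @param s a [spectra_set] (or a plain numeric matrix with rownames as ids).
#' @param k number of samples to select, `2 <= k <= n`.
#' @param center center columns before computing distances (default TRUE).
#' @return Character vector of `k` sample ids in selection order.
#' @export
kennard_stone <- function(s, k, center = TRUE) {
  if (inherits(s, "spectra_set")) {
    X <- s$absorbance
    ids <- s$sample_ids
  } else {
    X <- as.matrix(s)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(X)))
  }
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n (n = ", n, ")")
  if (center) X <- sweep(X, 2, colMeans(X))
  # full pairwise distance matrix; n here is modest (hundreds)
  D <- as.matrix(stats::dist(X))
  # seed: most distant pair; ties resolved to the lexicographically smallest
  # (i, j) index pair, i < j
  m <- max(D)
  cand <- which(D == m, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])
  remaining <- setdiff(seq_len(n), sel)
  while (length(sel) < k) {
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    best <- remaining[which.max(mind)]  # which.max takes the first (smallest index)
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
  }
  ids[sel]
}

#' Range-based calibration/validation split
#'
#' Splits samples into a calibration and a validation set "according to the
#' range of the chemical values": samples are ranked along the first
#' principal direction of the standardized reference-value matrix, the
#' per-parameter global extremes (min and max of every constituent) are
#' forced into the calibration set, and `n_val` validation samples are taken
#' at evenly spaced positions along the ranked interior.  Deterministic for
#' fixed input.
#'
#' @param ref a `reference_table` (see [reference_table]); every parameter
#'   column must be complete.
#' @param n_cal,n_val calibration / validation sizes; must sum to `nrow(ref)`
#'   and the validation set must be the minority (`n_val < n/2`).
#' @return A `split_plan`: list with `calibration_ids` and `validation_ids`.
#' @export
range_split <- function(ref, n_cal, n_val) {
  stopifnot(inherits(ref, "data.frame"))
  params <- setdiff(names(ref), c("sample_id", "replicate"))
  Y <- as.matrix(ref[params])
  if (anyNA(Y)) stop("reference table has missing values")
  n <- nrow(Y)
  if (n_cal + n_val != n)
    stop("n_cal + n_val (", n_cal + n_val, ") must equal n (", n, ")")
  if (n_val >= n / 2) stop("validation set must be the minority split")
  ids <- ref$sample_id
  # rank along the dominant direction of standardized constituent space
  Z <- scale(Y)
  Z[is.nan(Z)] <- 0
  score <- if (ncol(Z) == 1) Z[, 1] else stats::prcomp(Z, center = FALSE)$x[, 1]
  ord <- order(score, seq_len(n))  # ties by row order: deterministic
  # global per-parameter extremes are pinned to calibration
  pinned <- unique(unlist(lapply(params, function(p)
    c(which.min(Y[, p]), which.max(Y[, p])))))
  interior <- setdiff(ord, pinned)  # in rank order
  if (length(interior) < n_val)
    stop("too few non-extreme samples for the requested validation size")
  pick <- unique(round(seq(1, length(interior), length.out = n_val)))
  # rounding collisions are only possible at tiny n; pad deterministically
  i <- 1
  while (length(pick) < n_val) {
    pick <- unique(c(pick, i))
    i <- i + 1
  }
  val_idx <- interior[sort(pick)]
  structure(list(calibration_ids = ids[setdiff(seq_len(n), val_idx)],
                 validation_ids = ids[val_idx]),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> calibration: ", length(x$calibration_ids),
      ", validation: ", length(x$validation_ids), "\n", sep = "")
  invisible(x)
}

#' Write a split plan as a two-column audit CSV
#'
#' @param plan a `split_plan`.
#' @param path output CSV path (`sample_id,set`).
#' @export
write_split <- function(plan, path) {
  df <- data.frame(
    sample_id = c(plan$calibration_ids, plan$validation_ids),
    set = rep(c("calibration", "validation"),
              c(length(plan$calibration_ids), length(plan$validation_ids))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
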