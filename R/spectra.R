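#' Construct a spectra set
#'
#' The central data container of the package: a set of near-infrared
#' absorbance spectra, recorded as log(1/R) where R is reflectance, on a
#' shared wavenumber grid (cm^-1).  Wavenumbers are canonicalized to strictly
#' increasing order; the absorbance matrix is permuted accordingly.
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotone in either direction.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames, or `S1..Sn` when absent.
#' @return An object of class `spectra_set`: a list with elements
#'   `absorbance` (matrix with sample ids as rownames), `wavenumbers`
#'   (increasing) and `sample_ids`.
#' @export
spectra_set <- function(absorbance, wavenumbers, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(absorbance)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stop("sample_ids length (", length(sample_ids),
         ") does not match number of spectra (", nrow(absorbance), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(wavenumbers) != ncol(absorbance))
    stop("wavenumbers length (", length(wavenumbers),
         ") does not match number of spectral points (", ncol(absorbance), ")")
  d <- diff(wavenumbers)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    stop("wavenumbers must be strictly monotone")
  if (length(d) > 0 && all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  if (!all(is.finite(absorbance)))
    stop("absorbance contains non-finite values")
  rownames(absorbance) <- sample_ids
  colnames(absorbance) <- NULL
  structure(list(absorbance = absorbance,
                 wavenumbers = wavenumbers,
                 sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", length(x$sample_ids), " samples x ",
      length(x$wavenumbers), " points, ",
      format(min(x$wavenumbers)), "-", format(max(x$wavenumbers)),
      " cm-1\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# Subset a spectra_set by sample ids (i) and/or column index (j).
#' @export
`[.spectra_set` <- function(x, i, j) {
  A <- x$absorbance
  wn <- x$wavenumbers
  if (!missing(i)) A <- A[i, , drop = FALSE]
  if (!missing(j)) {
    A <- A[, j, drop = FALSE]
    wn <- wn[j]
  }
  spectra_set(A, wn, rownames(A))
}

#' Read spectra from a delimited text file
#'
#' Two dialects are supported.  `wide`: first column holds sample ids, the
#' remaining column headers are numeric wavenumbers (samples as rows).  A
#' transposed wide layout (first column numeric wavenumbers, remaining
#' headers sample ids) is detected and handled.  `long`: three columns
#' `sample`, `wavenumber`, `absorbance`.
#'
#' @param path file path (CSV; tab-delimited also accepted via `sep`).
#' @param dialect `"wide"` (default) or `"long"`.
#' @param sep field separator, default `","`.
#' @return A [spectra_set].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (dialect == "long") {
    need <- c("sample", "wavenumber", "absorbance")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    wn <- sort(unique(df$wavenumber))
    ids <- unique(as.character(df$sample))
    A <- matrix(NA_real_, length(ids), length(wn),
                dimnames = list(ids, NULL))
    A[cbind(match(as.character(df$sample), ids), match(df$wavenumber, wn))] <-
      df$absorbance
    if (anyNA(A)) stop("long table is ragged: not every sample has every wavenumber")
    return(spectra_set(A, wn, ids))
  }
  hdr <- names(df)[-1]
  hdr_num <- suppressWarnings(as.numeric(hdr))
  first_num <- suppressWarnings(as.numeric(as.character(df[[1]])))
  if (all(!is.na(hdr_num))) {
    # samples as rows
    ids <- as.character(df[[1]])
    A <- as.matrix(df[, -1, drop = FALSE])
    wn <- hdr_num
  } else if (all(!is.na(first_num))) {
    # samples as columns; first column is the wavenumber axis
    wn <- first_num
    A <- t(as.matrix(df[, -1, drop = FALSE]))
    ids <- hdr
  } else {
    stop("cannot interpret wide table: headers are not wavenumbers and the ",
         "first column is not a wavenumber axis")
  }
  if (!is.numeric(A)) {
    bad <- which(is.na(suppressWarnings(apply(A, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric absorbance cell at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  if (anyNA(A)) {
    bad <- which(is.na(A), arr.ind = TRUE)
    stop("missing/non-numeric absorbance at row ", bad[1, 1],
         ", column ", bad[1, 2])
  }
  spectra_set(A, wn, ids)
}

#' Write spectra to a wide CSV file
#'
#' Inverse of [read_spectra] (wide dialect): first column `sample_id`,
#' remaining headers the wavenumbers.  Values are written with full double
#' precision so that a read/write round trip is the identity to numeric
#' precision.
#'
#' @param s a [spectra_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = s$sample_ids, s$absorbance,
                   check.names = FALSE)
  names(df) <- c("sample_id", format(s$wavenumbers, digits = 15, trim = TRUE,
                                     scientific = FALSE))
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write spectra to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a reference-value table
#'
#' Reads per-sample constituent reference values (percent of dry matter) for
#' any subset of CP, NDF, ADF and WSC.  An optional `replicate` column marks
#' repeated laboratory measurements of the same sample; with
#' `average_replicates = TRUE` these are collapsed to their mean, and the
#' replicate-resolved table is retained in the `replicates` attribute for
#' laboratory-precision (SEL) estimation.
#'
#' @param path CSV path with columns `sample_id[, replicate], <parameters>`.
#' @param average_replicates collapse replicate rows to per-sample means
#'   (default `FALSE`: rows are used as given).
#' @param sep field separator.
#' @return A `reference_table`: a data.frame with `sample_id` plus one column
#'   per parameter; attribute `replicates` holds the replicate-resolved rows
#'   when a replicate column was present.
#' @export
read_reference <- function(path, average_replicates = FALSE, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  reference_table(df, average_replicates = average_replicates)
}

#' Build a reference table from a data.frame
#'
#' @param df data.frame with `sample_id`, optional `replicate`, and numeric
#'   parameter columns (%DM).
#' @param average_replicates collapse replicate rows to per-sample means.
#' @return A `reference_table` (see [read_reference]).
#' @export
reference_table <- function(df, average_replicates = FALSE) {
  if (!"sample_id" %in% names(df)) stop("reference table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  params <- setdiff(names(df), c("sample_id", "replicate"))
  if (length(params) == 0) stop("reference table has no parameter columns")
  for (p in params) {
    v <- df[[p]]
    if (all(is.na(v))) stop("parameter column ", p, " is all-missing")
    if (any(v < 0, na.rm = TRUE) || any(v > 100, na.rm = TRUE))
      stop("parameter ", p, " has values outside [0, 100] %DM")
  }
  replicates <- NULL
  if ("replicate" %in% names(df)) {
    replicates <- df
    counts <- table(df$sample_id)
    if (any(counts < 2))
      warning("samples with a single replicate: ",
              paste(names(counts)[counts < 2], collapse = ", "),
              " (SEL estimation needs >= 2)")
    if (average_replicates) {
      agg <- stats::aggregate(df[params], by = list(sample_id = df$sample_id),
                              FUN = mean)
      df <- agg[match(unique(df$sample_id), agg$sample_id), , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  if (!"replicate" %in% names(df) && anyDuplicated(df$sample_id))
    stop("duplicate sample ids in reference table (add a replicate column?)")
  out <- df[, c("sample_id", intersect(names(df), params)), drop = FALSE]
  attr(out, "replicates") <- replicates
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Align a spectra set and a reference table on shared sample ids
#'
#' Fails loudly on any mismatch rather than silently intersecting.
#'
#' @param s a [spectra_set].
#' @param ref a `reference_table`.
#' @return list with the spectra and reference rows in matching order.
#' @export
align_samples <- function(s, ref) {
  missing_ref <- setdiff(s$sample_ids, ref$sample_id)
  missing_spc <- setdiff(ref$sample_id, s$sample_ids)
  if (length(missing_ref) || length(missing_spc))
    stop("sample id mismatch between spectra and reference table; ",
         "spectra-only: [", paste(missing_ref, collapse = ", "),
         "], reference-only: [", paste(missing_spc, collapse = ", "), "]")
  ord <- match(s$sample_ids, ref$sample_id)
  ref2 <- ref[ord, , drop = FALSE]
  rownames(ref2) <- NULL
  list(spectra = s, reference = ref2)
}
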