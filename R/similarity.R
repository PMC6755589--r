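#' Tanimoto coefficient between two binary vectors
#'
#' `|a AND b| / |a OR b|`, the standard similarity for binary molecular
#' fingerprints. The undefined 0/0 case (both vectors all-zero) returns
#' `zero_value`, 0 by default: an empty fingerprint shares no features, and
#' this choice also prevents an all-zero SB-DFP from appearing maximally
#' similar to everything. Set `zero_value = 1` to match toolkits that use the
#' other convention.
#'
#' @param a,b 0/1 vectors of equal length, or [database_fingerprint()]
#'   objects.
#' @param zero_value value returned when both vectors are all-zero.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0), c(0, 1, 1))  # 1/3
#' @export
tanimoto <- function(a, b, zero_value = 0) {
  if (inherits(a, "DatabaseFingerprint")) a <- a$bits
  if (inherits(b, "DatabaseFingerprint")) b <- b$bits
  if (length(a) != length(b)) {
    stop("tanimoto: vectors differ in length", call. = FALSE)
  }
  a <- as.integer(a); b <- as.integer(b)
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) return(zero_value)
  inter / union
}

# internal: n x m matrix of Tanimoto similarities between the rows of two
# 0/1 matrices, via bit-count algebra (|A&B| = A B', |A|B| = |a|+|b|-|A&B|)
tanimoto_cross <- function(A, B, zero_value = 0) {
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  out <- ifelse(union == 0, zero_value, inter / union)
  out
}

#' Median intra-set Tanimoto similarity
#'
#' Median Tanimoto coefficient over all unordered distinct molecule pairs of
#' one data set (self-pairs excluded) — the diversity summary reported per
#' data set and the diagonal of the ACC similarity matrix.
#'
#' @param matrix a [bit_matrix()] with at least 2 molecules.
#' @param zero_value see [tanimoto()].
#' @return median similarity in \[0, 1\].
#' @export
intra_set_median <- function(matrix, zero_value = 0) {
  stopifnot(inherits(matrix, "BitMatrix"))
  n <- nrow(matrix$bits)
  if (n < 2L) {
    stop("intra-set median needs at least 2 molecules", call. = FALSE)
  }
  sims <- tanimoto_cross(matrix$bits, matrix$bits, zero_value)
  stats::median(sims[upper.tri(sims)])
}

#' All-compound-comparison (ACC) similarity between two data sets
#'
#' Median Tanimoto over the full cross product of molecule pairs when the
#' sets differ; for a set against itself the intra-set median over distinct
#' pairs is used, so ACC self-similarity typically does not reach 1.
#'
#' @param matA,matB [bit_matrix()] objects sharing a fingerprint scheme.
#' @param zero_value see [tanimoto()].
#' @return median similarity in \[0, 1\].
#' @export
acc_similarity <- function(matA, matB, zero_value = 0) {
  stopifnot(inherits(matA, "BitMatrix"), inherits(matB, "BitMatrix"))
  check_same_scheme(matA, matB)
  if (identical(matA$bits, matB$bits)) {
    return(intra_set_median(matA, zero_value))
  }
  stats::median(tanimoto_cross(matA$bits, matB$bits, zero_value))
}

#' Pairwise similarity matrix between compound data sets
#'
#' Builds the inter-dataset similarity matrix under one of three
#' methodologies: `ACC` (median Tanimoto over all cross-set compound pairs;
#' diagonal = intra-set median), `DFP` (each set condensed once with
#' [build_dfp()], pairwise Tanimoto between the condensed fingerprints;
#' diagonal exactly 1) or `SB-DFP` (same with [build_sbdfp()] against a
#' required reference profile).
#'
#' @param datasets named list of [bit_matrix()] objects on a common scheme.
#' @param methodology `"ACC"`, `"DFP"` or `"SB-DFP"`.
#' @param reference_profile [bit_count_profile()]; required for `SB-DFP`.
#' @param threshold DFP occurrence threshold (default 0.5).
#' @param alpha SB-DFP significance level (default 0.01).
#' @param zero_value see [tanimoto()].
#' @return A [similarity_matrix_object()].
#' @export
similarity_matrix <- function(datasets,
                              methodology = c("ACC", "DFP", "SB-DFP"),
                              reference_profile = NULL,
                              threshold = 0.5, alpha = 0.01,
                              zero_value = 0) {
  methodology <- match.arg(methodology)
  if (length(datasets) < 2L) {
    stop("need at least 2 data sets", call. = FALSE)
  }
  if (is.null(names(datasets)) || anyDuplicated(names(datasets))) {
    stop("datasets must be a uniquely named list", call. = FALSE)
  }
  for (d in datasets) {
    stopifnot(inherits(d, "BitMatrix"))
    check_same_scheme(datasets[[1]], d)
  }
  if (methodology == "SB-DFP") {
    if (is.null(reference_profile)) {
      stop("SB-DFP methodology requires a reference_profile", call. = FALSE)
    }
    check_same_scheme(datasets[[1]], reference_profile)
  }
  labels <- names(datasets)
  n <- length(datasets)
  vals <- matrix(0, n, n, dimnames = list(labels, labels))
  if (methodology == "ACC") {
    for (i in seq_len(n)) {
      vals[i, i] <- intra_set_median(datasets[[i]], zero_value)
      for (j in seq_len(i - 1L)) {
        s <- acc_similarity(datasets[[i]], datasets[[j]], zero_value)
        vals[i, j] <- vals[j, i] <- s
      }
    }
  } else {
    fps <- lapply(datasets, function(d) {
      prof <- count_bits(d)
      if (methodology == "DFP") build_dfp(prof, threshold)
      else build_sbdfp(prof, reference_profile, alpha)
    })
    for (i in seq_len(n)) {
      vals[i, i] <- 1
      for (j in seq_len(i - 1L)) {
        s <- tanimoto(fps[[i]], fps[[j]], zero_value)
        vals[i, j] <- vals[j, i] <- s
      }
    }
  }
  similarity_matrix_object(vals, labels, methodology,
                           datasets[[1]]$scheme_tag)
}

#' Convert a similarity matrix to distances
#'
#' Elementwise `distance = 1 - similarity`; symmetry is preserved. This is
#' the distance used for hierarchical clustering of data-set relationships.
#'
#' @param sim a [similarity_matrix_object()] or a plain numeric matrix with
#'   values in \[0, 1\].
#' @return numeric distance matrix with the same labels.
#' @export
to_distance <- function(sim) {
  values <- if (inherits(sim, "SimilarityMatrix")) sim$values
            else as.matrix(sim)
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  1 - values
}

#' Range summary of a similarity matrix
#'
#' Minimum, average, maximum and range (max - min) over the unique
#' off-diagonal entries (or all entries, with `include_diagonal = TRUE`).
#' The range of values in a similarity matrix measures the resolution of
#' the representation: a wider range discriminates data-set pairs better.
#'
#' @param sim a [similarity_matrix_object()].
#' @param include_diagonal include diagonal entries in the summary.
#' @return named list with `min`, `average`, `max`, `range`.
#' @export
matrix_range_summary <- function(sim, include_diagonal = FALSE) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  v <- sim$values
  vals <- if (include_diagonal) v[upper.tri(v, diag = TRUE)]
          else v[upper.tri(v)]
  list(min = min(vals), average = mean(vals), max = max(vals),
       range = max(vals) - min(vals))
}

#' Write / read a labeled similarity or distance matrix as TSV
#'
#' First row and first column carry the data-set names. Values are written
#' at 3 decimal places by default; pass `digits = NA` for full precision.
#'
#' @param sim a [similarity_matrix_object()] or plain labeled matrix.
#' @param path output file.
#' @param digits decimal places, or `NA` for full precision.
#' @export
write_matrix_tsv <- function(sim, path, digits = 3) {
  values <- if (inherits(sim, "SimilarityMatrix")) sim$values
            else as.matrix(sim)
  out <- if (is.na(digits)) values else round(values, digits)
  df <- data.frame(name = rownames(out), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv()` returns a labeled numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
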