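#' Binary fingerprint matrix
#'
#' Container for a set of molecules represented under one binary fingerprint
#' scheme: a molecules-by-bits 0/1 matrix plus unique molecule identifiers and
#' a scheme tag. Bit indices are 0-based everywhere in this package (internal
#' column `j` holds bit `j - 1`); serialized profiles carry an explicit
#' bit-index column so 1-based external sources can be ingested with an offset
#' flag (see [read_profile()]).
#'
#' @param rows integer matrix (or coercible) of 0/1 values, one row per
#'   molecule, one column per bit.
#' @param ids character vector of unique molecule identifiers, one per row.
#'   Defaults to `mol_0 .. mol_{n-1}`.
#' @param scheme_tag free-text fingerprint scheme label, e.g. `"MACCS-166"`,
#'   `"ECFP4-2048"` or `"synthetic"`. Cross-object operations require equal
#'   tags; a mismatch is an error, never a silent recycle.
#' @return An object of class `BitMatrix`: a list with elements `ids`,
#'   `n_bits`, `bits` (integer matrix with `ids` as rownames) and
#'   `scheme_tag`.
#' @seealso [count_bits()], [sample_bitmatrix()]
#' @export
bit_matrix <- function(rows, ids = NULL, scheme_tag = "synthetic") {
  rows <- as.matrix(rows)
  if (nrow(rows) < 1L || ncol(rows) < 1L) {
    stop("BitMatrix needs at least one molecule and one bit", call. = FALSE)
  }
  storage.mode(rows) <- "integer"
  if (anyNA(rows) || !all(rows == 0L | rows == 1L)) {
    stop("BitMatrix entries must all be 0 or 1", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("mol_", seq_len(nrow(rows)) - 1L)
  ids <- as.character(ids)
  if (length(ids) != nrow(rows)) {
    stop("length(ids) must equal the number of rows", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("molecule identifiers must be unique within a BitMatrix",
         call. = FALSE)
  }
  rownames(rows) <- ids
  colnames(rows) <- NULL
  structure(
    list(ids = ids, n_bits = ncol(rows), bits = rows,
         scheme_tag = as.character(scheme_tag)[1]),
    class = "BitMatrix"
  )
}

#' @export
print.BitMatrix <- function(x, ...) {
  cat(sprintf("BitMatrix: %d molecules x %d bits [%s], density %.3f\n",
              nrow(x$bits), x$n_bits, x$scheme_tag, mean(x$bits)))
  invisible(x)
}

#' @export
dim.BitMatrix <- function(x) dim(x$bits)

#' Per-bit "1"-count profile
#'
#' Summary of a compound collection as the number of molecules with each bit
#' set, out of `n_obs` molecules observed. Built on a reference collection it
#' carries the reference proportions (p_r, n_r) for SB-DFP construction; built
#' on a target set it carries (p_t, n_t).
#'
#' @param counts non-negative integer vector of per-bit "1"-counts.
#' @param n_obs number of molecules observed; every count must be `<= n_obs`.
#' @param scheme_tag fingerprint scheme label (see [bit_matrix()]).
#' @return An object of class `BitCountProfile`: list with `counts`, `n_obs`,
#'   `n_bits`, `scheme_tag`.
#' @seealso [count_bits()], [build_sbdfp()], [read_profile()]
#' @export
bit_count_profile <- function(counts, n_obs, scheme_tag = "synthetic") {
  counts <- as.numeric(counts)
  n_obs <- as.numeric(n_obs)[1]
  if (length(counts) < 1L) stop("counts must be non-empty", call. = FALSE)
  if (is.na(n_obs) || n_obs < 1) {
    stop("n_obs must be a positive integer", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts > n_obs)) {
    stop("counts must satisfy 0 <= count <= n_obs for every bit",
         call. = FALSE)
  }
  if (any(counts != round(counts)) || n_obs != round(n_obs)) {
    stop("counts and n_obs must be whole numbers", call. = FALSE)
  }
  structure(
    list(counts = counts, n_obs = n_obs, n_bits = length(counts),
         scheme_tag = as.character(scheme_tag)[1]),
    class = "BitCountProfile"
  )
}

#' @export
print.BitCountProfile <- function(x, ...) {
  cat(sprintf(
    "BitCountProfile: %d bits, n_obs = %s [%s], mean frequency %.3f\n",
    x$n_bits, format(x$n_obs, big.mark = ","), x$scheme_tag,
    mean(x$counts / x$n_obs)))
  invisible(x)
}

#' Proportions encoded by a profile
#'
#' @param profile a [bit_count_profile()].
#' @return numeric vector `counts / n_obs`, one proportion per bit.
#' @export
bit_proportions <- function(profile) {
  stopifnot(inherits(profile, "BitCountProfile"))
  profile$counts / profile$n_obs
}

#' Single-fingerprint condensation of a compound set
#'
#' The result of condensing a data set into one binary vector, either by the
#' 50%-threshold rule (DFP) or by per-bit statistical enrichment against a
#' reference collection (SB-DFP). Constructed by [build_dfp()] and
#' [build_sbdfp()]; direct construction is for deserialization.
#'
#' @param bits 0/1 vector.
#' @param method `"DFP"` or `"SB-DFP"`.
#' @param param for DFP the threshold fraction, for SB-DFP the significance
#'   level alpha.
#' @param n_source number of molecules condensed.
#' @param scheme_tag fingerprint scheme label.
#' @return An object of class `DatabaseFingerprint`.
#' @export
database_fingerprint <- function(bits, method = c("DFP", "SB-DFP"),
                                 param, n_source, scheme_tag = "synthetic") {
  method <- match.arg(method)
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || !all(bits == 0L | bits == 1L)) {
    stop("DatabaseFingerprint bits must all be 0 or 1", call. = FALSE)
  }
  structure(
    list(bits = bits, n_bits = length(bits), method = method,
         param = as.numeric(param)[1], n_source = as.integer(n_source)[1],
         scheme_tag = as.character(scheme_tag)[1]),
    class = "DatabaseFingerprint"
  )
}

#' @export
print.DatabaseFingerprint <- function(x, ...) {
  pname <- if (x$method == "DFP") "threshold" else "alpha"
  cat(sprintf(
    "DatabaseFingerprint (%s, %s = %g): %d of %d bits set [%s], from %d molecules\n",
    x$method, pname, x$param, sum(x$bits), x$n_bits, x$scheme_tag,
    x$n_source))
  invisible(x)
}

#' Inter-dataset similarity matrix
#'
#' Square symmetric matrix of pairwise similarities between named compound
#' data sets under one of the three methodologies: `ACC` (median Tanimoto over
#' all cross-set compound pairs; diagonal is the intra-set median and need not
#' be 1), `DFP` or `SB-DFP` (Tanimoto between condensed single fingerprints;
#' diagonal exactly 1).
#'
#' @param values square numeric matrix with entries in \[0, 1\].
#' @param labels data-set names; default taken from `rownames(values)`.
#' @param methodology `"ACC"`, `"DFP"` or `"SB-DFP"`.
#' @param scheme_tag fingerprint scheme label.
#' @return An object of class `SimilarityMatrix`.
#' @seealso [similarity_matrix()], [to_distance()]
#' @export
similarity_matrix_object <- function(values, labels = rownames(values),
                                     methodology = c("ACC", "DFP", "SB-DFP"),
                                     scheme_tag = "synthetic") {
  methodology <- match.arg(methodology)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("set_", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values) || anyDuplicated(labels)) {
    stop("labels must be unique and match the matrix dimension",
         call. = FALSE)
  }
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  if (methodology %in% c("DFP", "SB-DFP") && any(diag(values) != 1)) {
    stop("DFP/SB-DFP similarity matrices must have unit diagonal",
         call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values, methodology = methodology,
         scheme_tag = as.character(scheme_tag)[1]),
    class = "SimilarityMatrix"
  )
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("SimilarityMatrix (%s/%s): %d data sets\n",
              x$methodology, x$scheme_tag, length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

# internal: error unless two objects share a fingerprint scheme and width
check_same_scheme <- function(a, b) {
  if (!identical(a$scheme_tag, b$scheme_tag)) {
    stop(sprintf("fingerprint scheme mismatch: '%s' vs '%s'",
                 a$scheme_tag, b$scheme_tag), call. = FALSE)
  }
  if (!identical(a$n_bits, b$n_bits)) {
    stop(sprintf("bit-length mismatch: %d vs %d bits", a$n_bits, b$n_bits),
         call. = FALSE)
  }
  invisible(TRUE)
}
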