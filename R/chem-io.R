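#' Read a SMILES file
#'
#' One molecule per line: the SMILES string, optionally followed by
#' whitespace and an identifier. Blank lines and `#` comment lines are
#' skipped (the count of skipped lines is reported via a message). Records
#' without an identifier get `mol_<i>` where `i` is the 0-based line index.
#'
#' @param path path to a `.smi` file.
#' @return data.frame with columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("SMILES file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  skipped <- 0L
  ids <- character(0); smis <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) {
      skipped <- skipped + 1L
      next
    }
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    smis <- c(smis, parts[1])
    ids <- c(ids, if (length(parts) >= 2) parts[2]
             else paste0("mol_", i - 1L))
  }
  if (length(smis) == 0L) {
    stop(sprintf("no valid SMILES records in %s", path), call. = FALSE)
  }
  if (skipped > 0L) {
    message(sprintf("read_smiles: skipped %d blank/comment line(s)", skipped))
  }
  data.frame(id = ids, smiles = smis)
}

#' Compute fingerprints for SMILES records
#'
#' Chemistry adapter turning parsed SMILES into a [bit_matrix()] under one of
#' two schemes, via the ChemmineR/ChemmineOB (OpenBabel) toolkit:
#'
#' * `MACCS-166` — MACCS structural keys. The toolkit returns a padded
#'   256-position vector with keys 1..166 in the first 166 positions; the
#'   adapter keeps those and re-bases them to bit indices 0..165.
#' * `ECFP4-2048` — extended-connectivity fingerprint of diameter 4
#'   (radius 2). The toolkit folds to 4096 bits; the adapter folds once more
#'   to 2048 by OR-ing the two halves.
#'
#' Molecules the toolkit cannot process are dropped and listed in the
#' rejection report, never silently. Bit-level agreement with other
#' toolkits' MACCS/ECFP implementations is not promised, only internal
#' consistency. No standardization or desalting is applied beyond toolkit
#' sanitization.
#'
#' @param records data.frame with `id` and `smiles` (from [read_smiles()]).
#' @param scheme `"MACCS-166"` or `"ECFP4-2048"`.
#' @return list with `matrix` (a [bit_matrix()]) and `rejected` (data.frame
#'   of `id`, `smiles`, `reason` for unprocessable molecules).
#' @export
fingerprint_molecules <- function(records,
                                  scheme = c("MACCS-166", "ECFP4-2048")) {
  scheme <- match.arg(scheme)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint_molecules needs the ChemmineR and ChemmineOB packages; ",
         "precomputed fingerprints can be loaded with read_bitmatrix()",
         call. = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  ob_name <- if (scheme == "MACCS-166") "MACCS" else "ECFP4"

  rows <- list(); kept_ids <- character(0)
  rej <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]; smi <- records$smiles[i]
    fp <- tryCatch({
      smivec <- stats::setNames(smi, id)
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smivec))
      m <- ChemmineR::as.matrix(ChemmineR::fingerprintOB(sdf, ob_name))
      if (nrow(m) != 1L) stop("toolkit returned no fingerprint")
      as.integer(m[1, ])
    }, error = function(e) conditionMessage(e))
    if (is.character(fp)) {
      rej[[length(rej) + 1L]] <- data.frame(id = id, smiles = smi,
                                            reason = fp)
      next
    }
    rows[[length(rows) + 1L]] <- fp
    kept_ids <- c(kept_ids, id)
  }
  if (length(rows) == 0L) {
    stop("no molecule could be processed by the chemistry toolkit",
         call. = FALSE)
  }
  raw <- do.call(rbind, rows)
  bits <- switch(scheme,
    "MACCS-166" = raw[, 1:166, drop = FALSE],
    "ECFP4-2048" = {
      half <- ncol(raw) %/% 2L
      fold <- (raw[, 1:half, drop = FALSE] |
               raw[, (half + 1):(2 * half), drop = FALSE]) * 1L
      if (half != 2048L) stop("unexpected ECFP4 width from toolkit")
      fold
    })
  rejected <- if (length(rej)) do.call(rbind, rej)
              else data.frame(id = character(0), smiles = character(0),
                              reason = character(0))
  list(matrix = bit_matrix(bits, kept_ids, scheme), rejected = rejected)
}

# internal: hex packing of a 0/1 vector, 4 bits per character, bit (4c) is
# the most significant bit of character c; pad bits beyond n_bits are zero
bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (4 - n %% 4) %% 4
  b <- c(bits, rep(0L, pad))
  nib <- b[c(TRUE, FALSE, FALSE, FALSE)] * 8L +
         b[c(FALSE, TRUE, FALSE, FALSE)] * 4L +
         b[c(FALSE, FALSE, TRUE, FALSE)] * 2L +
         b[c(FALSE, FALSE, FALSE, TRUE)]
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[nib + 1L], collapse = "")
}

hex_to_bits <- function(hex, n_bits) {
  nib <- strtoi(strsplit(tolower(hex), "")[[1]], base = 16L)
  if (anyNA(nib)) stop("invalid hex fingerprint string", call. = FALSE)
  bits <- as.integer(rbind(nib %/% 8L, (nib %/% 4L) %% 2L,
                           (nib %/% 2L) %% 2L, nib %% 2L))
  if (length(bits) < n_bits || any(bits[-seq_len(n_bits)] != 0L)) {
    stop("hex fingerprint does not match the declared bit length",
         call. = FALSE)
  }
  bits[seq_len(n_bits)]
}

# internal: parse "#key=value key=value" header comment
parse_header <- function(line, path) {
  if (!startsWith(line, "#")) {
    stop(sprintf("%s: missing header comment line", path), call. = FALSE)
  }
  kv <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  pairs <- strsplit(kv, "=", fixed = TRUE)
  stats::setNames(vapply(pairs, `[`, "", 2), vapply(pairs, `[`, "", 1))
}

#' Write / read a fingerprint matrix as TSV
#'
#' Lossless round-trip format: a `#` header comment carrying `scheme_tag`,
#' `n_bits` and the `dialect`, a column-header row, then one row per
#' molecule with its identifier and its bits either as a 0/1 string
#' (`dialect = "bitstring"`) or packed 4-bits-per-character
#' (`dialect = "hex"`, most significant bit first). Both dialects decode
#' identically.
#'
#' @param matrix a [bit_matrix()].
#' @param path output file.
#' @param dialect `"bitstring"` or `"hex"`.
#' @export
write_bitmatrix <- function(matrix, path, dialect = c("bitstring", "hex")) {
  stopifnot(inherits(matrix, "BitMatrix"))
  dialect <- match.arg(dialect)
  enc <- if (dialect == "bitstring") {
    apply(matrix$bits, 1, paste, collapse = "")
  } else {
    apply(matrix$bits, 1, bits_to_hex)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scheme_tag=%s n_bits=%d dialect=%s",
                     matrix$scheme_tag, matrix$n_bits, dialect), con)
  writeLines("id\tbits", con)
  writeLines(paste(matrix$ids, enc, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_bitmatrix
#' @return `read_bitmatrix()` returns a [bit_matrix()].
#' @export
read_bitmatrix <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header(lines[1], path)
  n_bits <- as.integer(hdr[["n_bits"]])
  dialect <- hdr[["dialect"]]
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  ids <- character(length(body))
  rows <- matrix(0L, length(body), n_bits)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("%s: malformed row at line %d", path, i + 2L),
           call. = FALSE)
    }
    ids[i] <- parts[1]
    rows[i, ] <- if (dialect == "hex") hex_to_bits(parts[2], n_bits)
    else {
      b <- as.integer(strsplit(parts[2], "")[[1]])
      if (length(b) != n_bits || anyNA(b) || !all(b %in% c(0L, 1L))) {
        stop(sprintf("%s: malformed bitstring at line %d", path, i + 2L),
             call. = FALSE)
      }
      b
    }
  }
  bit_matrix(rows, ids, hdr[["scheme_tag"]])
}

#' Write / read a bit-count profile as TSV
#'
#' Header comment with `scheme_tag`, `n_bits`, `n_obs`; then a
#' `bit_index<TAB>count` row per bit. Bit indices are written 0-based; files
#' from 1-based external sources can be ingested with `index_base = 1`.
#'
#' @param profile a [bit_count_profile()].
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "BitCountProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scheme_tag=%s n_bits=%d n_obs=%.0f",
                     profile$scheme_tag, profile$n_bits, profile$n_obs), con)
  writeLines("bit_index\tcount", con)
  writeLines(sprintf("%d\t%.0f", seq_len(profile$n_bits) - 1L,
                     profile$counts), con)
  invisible(path)
}

#' @rdname write_profile
#' @param index_base 0 (default) or 1: the base of the bit-index column in
#'   the file being read.
#' @return `read_profile()` returns a [bit_count_profile()].
#' @export
read_profile <- function(path, index_base = 0) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header(lines[1], path)
  n_bits <- as.integer(hdr[["n_bits"]])
  n_obs <- as.numeric(hdr[["n_obs"]])
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_bits) {
    stop(sprintf("%s: expected %d bit rows, found %d", path, n_bits,
                 length(body)), call. = FALSE)
  }
  counts <- numeric(n_bits)
  seen <- logical(n_bits)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop(sprintf("%s: malformed row at line %d", path, i + 2L),
           call. = FALSE)
    }
    j <- as.integer(parts[1]) - as.integer(index_base) + 1L
    if (is.na(j) || j < 1L || j > n_bits || seen[j]) {
      stop(sprintf("%s: bad or duplicate bit index at line %d", path,
                   i + 2L), call. = FALSE)
    }
    seen[j] <- TRUE
    counts[j] <- as.numeric(parts[2])
  }
  bit_count_profile(counts, n_obs, hdr[["scheme_tag"]])
}

#' Write / read a condensed database fingerprint as TSV
#'
#' Single-row variant of the bit-matrix format, with `method`, `param` and
#' `n_source` carried in the header.
#'
#' @param dbfp a [database_fingerprint()].
#' @param path file path.
#' @export
write_dbfp <- function(dbfp, path) {
  stopifnot(inherits(dbfp, "DatabaseFingerprint"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "#scheme_tag=%s n_bits=%d method=%s param=%.17g n_source=%d",
    dbfp$scheme_tag, dbfp$n_bits, dbfp$method, dbfp$param, dbfp$n_source),
    con)
  writeLines("bits", con)
  writeLines(paste(dbfp$bits, collapse = ""), con)
  invisible(path)
}

#' @rdname write_dbfp
#' @return `read_dbfp()` returns a [database_fingerprint()].
#' @export
read_dbfp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_header(lines[1], path)
  bits <- as.integer(strsplit(lines[3], "")[[1]])
  if (length(bits) != as.integer(hdr[["n_bits"]])) {
    stop(sprintf("%s: bit count does not match header", path), call. = FALSE)
  }
  database_fingerprint(bits, hdr[["method"]],
                       as.numeric(hdr[["param"]]),
                       as.integer(hdr[["n_source"]]), hdr[["scheme_tag"]])
}
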