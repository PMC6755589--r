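#' Specification for the synthetic bit-matrix generator
#'
#' Defines a per-bit Bernoulli model of a fingerprint population: every bit
#' of every molecule is drawn independently with its own probability. A
#' designated subset of "enriched" bits carries an elevated probability used
#' when sampling active-like sets, planting a known signal that the SB-DFP
#' construction should recover.
#'
#' The default base spectrum, `qbeta(ppoints(n_bits), 1.2, 2.6)`, is skewed
#' toward rare bits with a mean frequency near 0.31 — the set-bit density
#' typical of MACCS fingerprints of drug-like molecules. The default
#' dimensions (166 bits, reference of one million observations, targets of
#' a few hundred molecules) echo the scales at which the method is used.
#'
#' Bits are independent by construction, which is exactly what the per-bit
#' test assumes; real fingerprints have correlated bits. For stress tests a
#' block-correlated mode is available: bits in blocks of `block_size` share
#' a latent Bernoulli event with coupling `block_rho`, inducing positive
#' within-block correlation while preserving each marginal probability.
#'
#' @param n_bits fingerprint length; default 166.
#' @param base_probs per-bit Bernoulli probabilities; default the beta
#'   quantile spectrum above.
#' @param enriched_bits 0-based indices of bits enriched in active sets.
#' @param enriched_probs probabilities for the enriched bits when sampling
#'   with `use_enriched = TRUE`; each must be `>=` its base probability.
#' @param block_size,block_rho optional block-correlation mode; `block_rho`
#'   in \[0, 1\), 0 = independent (default).
#' @param scheme_tag scheme label stamped on generated objects.
#' @return an object of class `GeneratorSpec`.
#' @export
generator_spec <- function(n_bits = 166,
                           base_probs = stats::qbeta(
                             stats::ppoints(n_bits), 1.2, 2.6),
                           enriched_bits = integer(0),
                           enriched_probs = numeric(0),
                           block_size = 1, block_rho = 0,
                           scheme_tag = "synthetic") {
  if (length(base_probs) != n_bits) {
    stop("base_probs must have one entry per bit", call. = FALSE)
  }
  if (anyNA(base_probs) || any(base_probs < 0) || any(base_probs > 1)) {
    stop("base_probs must lie in [0, 1]", call. = FALSE)
  }
  enriched_bits <- as.integer(enriched_bits)
  if (length(enriched_bits) != length(enriched_probs)) {
    stop("enriched_bits and enriched_probs must align", call. = FALSE)
  }
  if (any(enriched_bits < 0) || any(enriched_bits >= n_bits) ||
      anyDuplicated(enriched_bits)) {
    stop("enriched_bits must be unique 0-based indices below n_bits",
         call. = FALSE)
  }
  if (any(enriched_probs < 0) || any(enriched_probs > 1)) {
    stop("enriched_probs must lie in [0, 1]", call. = FALSE)
  }
  if (any(enriched_probs < base_probs[enriched_bits + 1L])) {
    stop("enriched probabilities must not fall below base probabilities",
         call. = FALSE)
  }
  if (block_rho < 0 || block_rho >= 1 || block_size < 1) {
    stop("block_rho must lie in [0, 1) and block_size be >= 1",
         call. = FALSE)
  }
  structure(
    list(n_bits = as.integer(n_bits), base_probs = as.numeric(base_probs),
         enriched_bits = enriched_bits,
         enriched_probs = as.numeric(enriched_probs),
         block_size = as.integer(block_size),
         block_rho = as.numeric(block_rho),
         scheme_tag = as.character(scheme_tag)[1]),
    class = "GeneratorSpec"
  )
}

# internal: effective per-bit probabilities
spec_probs <- function(spec, use_enriched) {
  p <- spec$base_probs
  if (use_enriched && length(spec$enriched_bits)) {
    p[spec$enriched_bits + 1L] <- spec$enriched_probs
  }
  p
}

# internal: run expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Sample a synthetic fingerprint matrix
#'
#' Draws `n_molecules` fingerprints from the spec's per-bit Bernoulli model,
#' reproducibly under the given seed. With `use_enriched = TRUE` the
#' enriched bits use their elevated probabilities (an "active-like" set).
#' In block-correlated mode each molecule draws one latent event per block;
#' with probability `block_rho` all bits of the block copy the latent event
#' thresholded by their own probability, inducing positive correlation
#' without changing the marginals.
#'
#' @param spec a [generator_spec()].
#' @param n_molecules number of fingerprints to draw.
#' @param use_enriched use the enriched probabilities; default `FALSE`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param id_prefix identifier prefix for the generated molecules.
#' @return a [bit_matrix()].
#' @export
sample_bitmatrix <- function(spec, n_molecules, use_enriched = FALSE,
                             seed = 1, id_prefix = "mol") {
  stopifnot(inherits(spec, "GeneratorSpec"))
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  p <- spec_probs(spec, use_enriched)
  nb <- spec$n_bits
  rows <- with_local_seed(seed, {
    m <- matrix(
      stats::rbinom(n_molecules * nb, 1L, rep(p, each = n_molecules)),
      nrow = n_molecules, ncol = nb)
    if (spec$block_rho > 0 && spec$block_size > 1) {
      block <- (seq_len(nb) - 1L) %/% spec$block_size
      for (b in unique(block)) {
        cols <- which(block == b)
        latent <- stats::runif(n_molecules)       # shared event per block
        couple <- stats::runif(n_molecules) < spec$block_rho
        for (j in cols) {
          m[couple, j] <- as.integer(latent[couple] < p[j])
        }
      }
    }
    m
  })
  bit_matrix(rows, paste0(id_prefix, "_", seq_len(n_molecules) - 1L),
             spec$scheme_tag)
}

#' Reference bit-count profile implied by a generator spec
#'
#' Either the exact expected counts `round(p * n_obs)` (mode `"exact"`, the
#' deterministic reference used in calibration experiments) or counts
#' sampled from `Binomial(n_obs, p)` (mode `"sampled"`).
#'
#' @param spec a [generator_spec()].
#' @param n_obs number of reference observations.
#' @param mode `"exact"` or `"sampled"`.
#' @param seed seed for `"sampled"` mode.
#' @return a [bit_count_profile()] built on the base probabilities.
#' @export
reference_profile_from_spec <- function(spec, n_obs = 1e6,
                                        mode = c("exact", "sampled"),
                                        seed = 1) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  mode <- match.arg(mode)
  if (n_obs < 1) stop("n_obs must be >= 1", call. = FALSE)
  p <- spec$base_probs
  counts <- if (mode == "exact") round(p * n_obs)
            else with_local_seed(seed, stats::rbinom(spec$n_bits, n_obs, p))
  bit_count_profile(counts, n_obs, spec$scheme_tag)
}

#' Build a complete synthetic screening fixture
#'
#' Actives are sampled with the enriched probabilities, decoys and the
#' reference profile from the base probabilities, with disjoint identifier
#' namespaces — a planted-signal benchmark input for [benchmark()].
#'
#' @param spec a [generator_spec()].
#' @param n_actives,n_decoys set sizes.
#' @param seed integer seed; actives, decoys and (in sampled mode) the
#'   reference use distinct derived substreams.
#' @param reference_n_obs reference collection size; default one million.
#' @param reference_mode `"exact"` (default) or `"sampled"`.
#' @return list with `actives`, `decoys` ([bit_matrix()]) and `reference`
#'   ([bit_count_profile()]).
#' @export
make_screening_fixture <- function(spec, n_actives, n_decoys, seed = 1,
                                   reference_n_obs = 1e6,
                                   reference_mode = "exact") {
  stopifnot(inherits(spec, "GeneratorSpec"))
  list(
    actives = sample_bitmatrix(spec, n_actives, use_enriched = TRUE,
                               seed = replicate_seed(seed, 1),
                               id_prefix = "act"),
    decoys = sample_bitmatrix(spec, n_decoys, use_enriched = FALSE,
                              seed = replicate_seed(seed, 2),
                              id_prefix = "dec"),
    reference = reference_profile_from_spec(
      spec, reference_n_obs, mode = reference_mode,
      seed = replicate_seed(seed, 3))
  )
}
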