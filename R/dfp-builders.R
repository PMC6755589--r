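#' Count bit occurrences in a fingerprint matrix
#'
#' Tallies, for every bit position, how many molecules in the matrix have the
#' bit set. This per-bit occurrence frequency is the raw material of both
#' database-fingerprint constructions.
#'
#' @param matrix a [bit_matrix()] with at least one row.
#' @return A [bit_count_profile()] with `counts[j]` = column sum of bit `j`
#'   and `n_obs` = number of molecules; the scheme tag is propagated.
#' @examples
#' m <- bit_matrix(rbind(c(1, 1, 0), c(0, 1, 1)))
#' count_bits(m)$counts  # 1 2 1
#' @export
count_bits <- function(matrix) {
  stopifnot(inherits(matrix, "BitMatrix"))
  if (nrow(matrix$bits) < 1L) {
    stop("cannot profile an empty BitMatrix: no observations", call. = FALSE)
  }
  bit_count_profile(colSums(matrix$bits), nrow(matrix$bits),
                    matrix$scheme_tag)
}

# internal vectorized core of the pooled two-proportion Z-test.
# Degenerate pooled proportion (0 or 1 forces p_t == p_r): z = 0, p = 0.5,
# the continuous limit of the equal-proportion case.
ztest_core <- function(count_t, n_t, count_r, n_r) {
  p_t <- count_t / n_t
  p_r <- count_r / n_r
  pooled <- (count_t + count_r) / (n_t + n_r)
  denom <- sqrt(pooled * (1 - pooled) * (1 / n_t + 1 / n_r))
  z <- ifelse(denom == 0, 0, (p_t - p_r) / denom)
  p <- ifelse(denom == 0, 0.5, stats::pnorm(z, lower.tail = FALSE))
  list(z = z, p_one_sided = p, pooled_p = pooled, p_t = p_t, p_r = p_r)
}

check_count_pair <- function(count, n, what) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop(sprintf("n_%s must be a positive integer", what), call. = FALSE)
  }
  if (anyNA(count) || any(count < 0) || any(count > n) ||
      any(count != round(count))) {
    stop(sprintf("count_%s must be an integer in [0, n_%s]", what, what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided two-proportion Z-test for bit enrichment
#'
#' Tests whether the proportion of molecules carrying a bit in a target set
#' (`count_t` of `n_t`) is larger than in a reference collection (`count_r`
#' of `n_r`), using the pooled-variance normal approximation
#' \deqn{Z = \frac{p_t - p_r}{\sqrt{P(1-P)\,(1/n_t + 1/n_r)}}, \qquad
#'       P = \frac{n_t p_t + n_r p_r}{n_t + n_r}.}
#' The one-sided p-value is `1 - pnorm(Z)` (alternative: target proportion is
#' larger). When the pooled proportion is 0 or 1 — which forces
#' `p_t == p_r` — the statistic is defined as 0 and the p-value as 0.5.
#'
#' @param count_t,n_t "1"-count and size of the target set.
#' @param count_r,n_r "1"-count and size of the reference collection.
#' @return An object of class `ZTestResult`: list with `z`, `p_one_sided`,
#'   `pooled_p`, `p_t`, `p_r`.
#' @examples
#' # 268 of 350 target molecules vs 10,892,579 of 15,403,690 reference
#' two_proportion_ztest(268, 350, 10892579, 15403690)$p_one_sided  # ~0.008
#' @export
two_proportion_ztest <- function(count_t, n_t, count_r, n_r) {
  check_count_pair(count_t, n_t, "t")
  check_count_pair(count_r, n_r, "r")
  stopifnot(length(count_t) == 1, length(count_r) == 1)
  res <- ztest_core(count_t, n_t, count_r, n_r)
  structure(res, class = "ZTestResult")
}

#' @export
print.ZTestResult <- function(x, ...) {
  cat(sprintf(
    "two-proportion Z-test: z = %.4f, one-sided p = %.4g (p_t = %.4f, p_r = %.4f, pooled = %.4f)\n",
    x$z, x$p_one_sided, x$p_t, x$p_r, x$pooled_p))
  invisible(x)
}

#' Build the classic database fingerprint (DFP)
#'
#' Sets bit `j` when it is present in at least `threshold` of the molecules
#' (default one half). The comparison is `>=`, so an exact tie at the
#' threshold sets the bit.
#'
#' @param profile a [bit_count_profile()] of the data set.
#' @param threshold occurrence fraction in (0, 1\]; default 0.5.
#' @return A [database_fingerprint()] with `method = "DFP"`.
#' @examples
#' p <- bit_count_profile(c(1, 2, 0), 2)
#' build_dfp(p)$bits  # 1 1 0
#' @export
build_dfp <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "BitCountProfile"))
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  bits <- as.integer(profile$counts / profile$n_obs >= threshold)
  database_fingerprint(bits, "DFP", threshold, profile$n_obs,
                       profile$scheme_tag)
}

#' Build the statistical-based database fingerprint (SB-DFP)
#'
#' Sets bit `j` only when its "1"-frequency in the target set is
#' statistically higher than in the reference collection: the one-sided
#' pooled two-proportion Z-test of [two_proportion_ztest()] must return
#' `p_one_sided` strictly below `alpha`. A merely larger target proportion is
#' not enough — the excess must clear the significance bar, which depends on
#' the target set size. No multiple-testing correction is applied across
#' bits; `alpha` is a tunable whose default (0.01, a 99% confidence level) is
#' the value that performed best in downstream similarity searching.
#'
#' @param target_profile [bit_count_profile()] of the target data set.
#' @param reference_profile [bit_count_profile()] of the reference
#'   collection; must share `n_bits` and `scheme_tag` with the target.
#' @param alpha significance level in (0, 1); default 0.01.
#' @return A [database_fingerprint()] with `method = "SB-DFP"`.
#' @examples
#' tgt <- bit_count_profile(c(268, 248), 350, "MACCS-166")
#' ref <- bit_count_profile(c(10892579, 10892579), 15403690, "MACCS-166")
#' build_sbdfp(tgt, ref)$bits  # 1 0
#' @export
build_sbdfp <- function(target_profile, reference_profile, alpha = 0.01) {
  stopifnot(inherits(target_profile, "BitCountProfile"),
            inherits(reference_profile, "BitCountProfile"))
  check_same_scheme(target_profile, reference_profile)
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly within (0, 1)", call. = FALSE)
  }
  res <- ztest_core(target_profile$counts, target_profile$n_obs,
                    reference_profile$counts, reference_profile$n_obs)
  bits <- as.integer(res$p_one_sided < alpha)
  database_fingerprint(bits, "SB-DFP", alpha, target_profile$n_obs,
                       target_profile$scheme_tag)
}

#' Smallest significant bit-occurrence count
#'
#' For a target set of `n_t` molecules and a fixed reference count, finds the
#' smallest integer occurrence `k` for which the one-sided test declares the
#' target proportion significantly higher (`p < alpha`), i.e. the minimum
#' number of molecules that must carry a bit for it to enter the SB-DFP.
#' Uses binary search, justified by the monotonicity of the p-value in the
#' target count, and falls back to a linear scan if the boundary found does
#' not verify numerically.
#'
#' @inheritParams two_proportion_ztest
#' @param alpha significance level in (0, 1).
#' @return The smallest qualifying integer in `[0, n_t]`, or `NA_integer_`
#'   when no count up to `n_t` reaches significance.
#' @examples
#' min_significant_count(350, 10892579, 15403690, 0.01)  # 268
#' @export
min_significant_count <- function(n_t, count_r, n_r, alpha = 0.01) {
  check_count_pair(0, n_t, "t")
  check_count_pair(count_r, n_r, "r")
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly within (0, 1)", call. = FALSE)
  }
  sig <- function(k) ztest_core(k, n_t, count_r, n_r)$p_one_sided < alpha
  if (!sig(n_t)) return(NA_integer_)
  lo <- 0; hi <- n_t  # invariant: sig(hi) TRUE
  if (sig(lo)) return(0L)
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (sig(mid)) hi <- mid else lo <- mid
  }
  # verify the boundary; a numerically non-monotone p-value would break it
  if (sig(hi) && !sig(hi - 1)) return(as.integer(hi))
  for (k in 0:n_t) if (sig(k)) return(as.integer(k))
  NA_integer_
}

#' Sweep SB-DFP construction over significance levels
#'
#' Builds one SB-DFP per significance level, for inspecting how the bit
#' density of the representation responds to the confidence level. The
#' default grid corresponds to confidence levels 90/95/99/99.5/99.9%.
#'
#' @inheritParams build_sbdfp
#' @param alphas numeric vector of levels in (0, 1).
#' @return A named list of [database_fingerprint()] objects, one per alpha.
#' @export
sbdfp_alpha_sweep <- function(target_profile, reference_profile,
                              alphas = c(0.10, 0.05, 0.01, 0.005, 0.001)) {
  out <- lapply(alphas, function(a)
    build_sbdfp(target_profile, reference_profile, a))
  names(out) <- formatC(alphas, format = "g")
  out
}
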