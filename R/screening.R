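#' 1-NN similarity scores against a multi-compound query
#'
#' Scores each library compound by its maximum Tanimoto similarity to any of
#' the query compounds (nearest-neighbour data fusion with the MAX rule).
#'
#' @param query non-empty [bit_matrix()] of query compounds.
#' @param library [bit_matrix()] of the search set, same scheme.
#' @param zero_value see [tanimoto()].
#' @return numeric score vector named by library compound identifier.
#' @export
knn_scores <- function(query, library, zero_value = 0) {
  stopifnot(inherits(query, "BitMatrix"), inherits(library, "BitMatrix"))
  check_same_scheme(query, library)
  if (nrow(query$bits) < 1L) stop("query is empty", call. = FALSE)
  sims <- tanimoto_cross(library$bits, query$bits, zero_value)
  out <- apply(sims, 1, max)
  names(out) <- library$ids
  out
}

#' Single-fingerprint similarity scores
#'
#' Scores each library compound by its Tanimoto similarity to one condensed
#' database fingerprint (DFP or SB-DFP), giving a single similarity value per
#' compound.
#'
#' @param dbfp a [database_fingerprint()].
#' @param library [bit_matrix()] of the search set, same scheme.
#' @param zero_value see [tanimoto()].
#' @return numeric score vector named by library compound identifier.
#' @export
single_fp_scores <- function(dbfp, library, zero_value = 0) {
  stopifnot(inherits(dbfp, "DatabaseFingerprint"),
            inherits(library, "BitMatrix"))
  check_same_scheme(dbfp, library)
  q <- matrix(dbfp$bits, nrow = 1)
  out <- drop(tanimoto_cross(library$bits, q, zero_value))
  names(out) <- library$ids
  out
}

# internal: deterministic ranking order — descending score, ties broken by
# ascending compound identifier (never by input position)
rank_order <- function(scores, ids) {
  order(-scores, ids)
}

#' Compound recovery rate at a fixed selection size
#'
#' Fraction of all actives found among the top `selection_size` compounds
#' after sorting by descending score. The default selection size equals the
#' number of actives in the library (the "number of available ADCs"
#' convention), making RR an early-enrichment measure. Ties at the cutoff
#' are resolved deterministically by ascending compound identifier.
#'
#' @param scores numeric score per library compound.
#' @param labels 0/1 per compound, 1 = active.
#' @param selection_size number of top compounds selected; default
#'   `sum(labels)`.
#' @param ids compound identifiers for tie-breaking; default
#'   `names(scores)` or the position index.
#' @return recovery rate in \[0, 1\].
#' @export
recovery_rate <- function(scores, labels,
                          selection_size = sum(labels == 1), ids = NULL) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_act <- sum(labels == 1)
  if (n_act == 0) stop("no actives in the library", call. = FALSE)
  if (selection_size < 1 || selection_size > length(scores)) {
    stop("selection_size must lie in [1, library size]", call. = FALSE)
  }
  if (is.null(ids)) ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("%09d", seq_along(scores))
  sel <- rank_order(scores, ids)[seq_len(selection_size)]
  sum(labels[sel] == 1) / n_act
}

#' ROC curve and AUC of a screening run
#'
#' The AUC is computed rank-based (Mann-Whitney): the probability that a
#' random active outscores a random decoy, with tied scores credited one
#' half. Single-fingerprint searches produce many tied scores, for which the
#' half-credit convention is the unbiased choice. The curve is built over
#' the distinct score thresholds (descending), so tied blocks appear as
#' diagonal segments and the trapezoidal area under the returned curve
#' equals the rank-based AUC.
#'
#' @param scores numeric score per library compound.
#' @param labels 0/1 per compound, 1 = active. At least one of each class.
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one active and one decoy", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties with 0.5 credit
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))  # last of each tie block
  curve <- data.frame(fpr = c(0, fp[block_end] / n0),
                      tpr = c(0, tp[block_end] / n1))
  list(auc = auc, curve = curve)
}

# internal: per-replicate seed derived from the top-level seed so replicate
# r is reproducible independently of n_reps; kept below 2^31
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 16807) %% 2147483647)
}

#' Repeated-random-query similarity-search benchmark
#'
#' The benchmark protocol for comparing search strategies on one activity
#' class: in each of `n_reps` replicates, `query_size` actives are drawn at
#' random (without replacement) as the query; all remaining actives become
#' the active database compounds (ADCs) and are pooled with the decoys into
#' the search set. The set is scored under three strategies — 1-NN (max
#' Tanimoto to any query compound), DFP and SB-DFP (single condensed
#' fingerprint built from the query compounds only) — and each run is
#' summarised by its recovery rate at a selection of size #ADCs and its ROC
#' AUC.
#'
#' @param actives [bit_matrix()] of active compounds
#'   (`> query_size` of them).
#' @param decoys [bit_matrix()] of decoys, identifiers disjoint from the
#'   actives.
#' @param reference_profile [bit_count_profile()] for SB-DFP construction.
#' @param n_reps number of random query replicates; default 100.
#' @param query_size compounds per query; default 10.
#' @param alpha SB-DFP significance level; default 0.01.
#' @param threshold DFP threshold; default 0.5.
#' @param seed top-level seed; each replicate derives its own substream, so
#'   replicate `r` is identical whatever `n_reps` is.
#' @param selection_size RR selection size; default (`NULL`) the per-replicate
#'   ADC count.
#' @return list of class `ScreeningBenchmark` with `replicates` (data.frame:
#'   replicate, strategy, rr, auc) and `summary` (data.frame: strategy,
#'   mean/sd of RR and AUC over replicates).
#' @export
benchmark <- function(actives, decoys, reference_profile,
                      n_reps = 100, query_size = 10,
                      alpha = 0.01, threshold = 0.5, seed = 1,
                      selection_size = NULL) {
  stopifnot(inherits(actives, "BitMatrix"), inherits(decoys, "BitMatrix"),
            inherits(reference_profile, "BitCountProfile"))
  check_same_scheme(actives, decoys)
  check_same_scheme(actives, reference_profile)
  n_act <- nrow(actives$bits)
  if (n_act <= query_size) {
    stop("need more actives than the query size", call. = FALSE)
  }
  if (any(actives$ids %in% decoys$ids)) {
    stop("actives and decoys must have disjoint identifiers", call. = FALSE)
  }

  strategies <- c("1-NN", "DFP", "SB-DFP")
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(replicate_seed(seed, r))
    qidx <- sample.int(n_act, query_size)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

    query <- bit_matrix(actives$bits[qidx, , drop = FALSE],
                        actives$ids[qidx], actives$scheme_tag)
    adc <- bit_matrix(actives$bits[-qidx, , drop = FALSE],
                      actives$ids[-qidx], actives$scheme_tag)
    lib <- bit_matrix(rbind(decoys$bits, adc$bits),
                      c(decoys$ids, adc$ids), actives$scheme_tag)
    labels <- c(rep(0L, nrow(decoys$bits)), rep(1L, nrow(adc$bits)))
    sel <- if (is.null(selection_size)) nrow(adc$bits) else selection_size

    qprof <- count_bits(query)
    score_sets <- list(
      "1-NN" = knn_scores(query, lib),
      "DFP" = single_fp_scores(build_dfp(qprof, threshold), lib),
      "SB-DFP" = single_fp_scores(
        build_sbdfp(qprof, reference_profile, alpha), lib)
    )
    rows[[r]] <- data.frame(
      replicate = r,
      strategy = strategies,
      rr = vapply(strategies, function(s)
        recovery_rate(score_sets[[s]], labels, sel), numeric(1)),
      auc = vapply(strategies, function(s)
        roc_auc(score_sets[[s]], labels)$auc, numeric(1)),
      row.names = NULL
    )
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(strategies, function(s) {
    sub <- reps[reps$strategy == s, ]
    data.frame(strategy = s,
               rr_mean = mean(sub$rr), rr_sd = stats::sd(sub$rr),
               auc_mean = mean(sub$auc), auc_sd = stats::sd(sub$auc))
  }))
  structure(list(replicates = reps, summary = summ,
                 n_reps = n_reps, query_size = query_size,
                 alpha = alpha, threshold = threshold, seed = seed),
            class = "ScreeningBenchmark")
}

#' @export
print.ScreeningBenchmark <- function(x, ...) {
  cat(sprintf("Similarity-search benchmark: %d replicates, query size %d\n",
              x$n_reps, x$query_size))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s RR = %.3f (%.3f)   AUC = %.3f (%.3f)\n",
                s$strategy[i], s$rr_mean[i], s$rr_sd[i],
                s$auc_mean[i], s$auc_sd[i]))
  }
  invisible(x)
}

#' Pairwise strategy comparison over benchmark replicates
#'
#' Flags, per metric, which strategies are statistically indistinguishable
#' from the best one across the replicate values, using a two-sided Welch
#' t-test at `level`.
#'
#' @param bench a [benchmark()] result.
#' @param metric `"auc"` or `"rr"`.
#' @param level significance level for the Welch test; default 0.05.
#' @return data.frame with per-strategy mean, the p-value of the Welch test
#'   against the best strategy, and a logical `best` column.
#' @export
best_strategy <- function(bench, metric = c("auc", "rr"), level = 0.05) {
  stopifnot(inherits(bench, "ScreeningBenchmark"))
  metric <- match.arg(metric)
  reps <- bench$replicates
  strategies <- unique(reps$strategy)
  means <- vapply(strategies, function(s)
    mean(reps[reps$strategy == s, metric]), numeric(1))
  top <- strategies[which.max(means)]
  pval <- vapply(strategies, function(s) {
    if (s == top) return(1)
    stats::t.test(reps[reps$strategy == top, metric],
                  reps[reps$strategy == s, metric])$p.value
  }, numeric(1))
  data.frame(strategy = strategies, mean = unname(means),
             p_vs_best = unname(pval),
             best = unname(pval >= level))
}

#' Benchmark sweep over SB-DFP significance levels
#'
#' Repeats [benchmark()] for each alpha in a grid (only the SB-DFP strategy
#' is affected; 1-NN and DFP results are reported once per alpha for
#' reference) and tabulates the summary per level.
#'
#' @inheritParams benchmark
#' @param alphas significance levels to test; the default grid corresponds
#'   to confidence levels 90/95/99/99.5/99.9%.
#' @return data.frame: one row per (alpha, strategy) with summary columns.
#' @export
benchmark_alpha_sweep <- function(actives, decoys, reference_profile,
                                  alphas = c(0.10, 0.05, 0.01, 0.005, 0.001),
                                  n_reps = 100, query_size = 10,
                                  threshold = 0.5, seed = 1,
                                  selection_size = NULL) {
  out <- lapply(alphas, function(a) {
    b <- benchmark(actives, decoys, reference_profile,
                   n_reps = n_reps, query_size = query_size,
                   alpha = a, threshold = threshold, seed = seed,
                   selection_size = selection_size)
    cbind(alpha = a, b$summary)
  })
  do.call(rbind, out)
}
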