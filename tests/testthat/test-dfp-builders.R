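test_that("the pooled Z-test reproduces the documented bit-100 case", {
  res <- two_proportion_ztest(268, 350, 10892579, 15403690)
  expect_equal(res$p_t, 268 / 350)
  expect_equal(res$p_r, 0.707, tolerance = 1e-3)
  expect_lt(abs(res$p_one_sided - 0.008), 1e-3)

  res2 <- two_proportion_ztest(248, 350, 10892579, 15403690)
  expect_lt(abs(res2$p_one_sided - 0.476), 1e-3)
  # larger target proportion, yet not significant at 0.01
  expect_gt(res2$p_t, res2$p_r)
  expect_gt(res2$p_one_sided, 0.01)
})

test_that("equal and degenerate proportions give z = 0, p = 0.5", {
  eq <- two_proportion_ztest(50, 100, 500, 1000)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_sided, 0.5)

  deg0 <- two_proportion_ztest(0, 100, 0, 1000)
  expect_equal(deg0$z, 0)
  expect_equal(deg0$p_one_sided, 0.5)
  expect_equal(deg0$pooled_p, 0)

  deg1 <- two_proportion_ztest(100, 100, 1000, 1000)
  expect_equal(deg1$p_one_sided, 0.5)
})

test_that("Z-test validates its count arguments", {
  expect_error(two_proportion_ztest(-1, 10, 5, 10), "count_t")
  expect_error(two_proportion_ztest(11, 10, 5, 10), "count_t")
  expect_error(two_proportion_ztest(5, 10, 11, 10), "count_r")
  expect_error(two_proportion_ztest(5, 0, 5, 10), "n_t")
})

test_that("pooled proportion sits between the two sample proportions", {
  set.seed(3)
  for (rep in 1:50) {
    nt <- sample(1:50, 1); nr <- sample(1:500, 1)
    ct <- sample(0:nt, 1); cr <- sample(0:nr, 1)
    res <- two_proportion_ztest(ct, nt, cr, nr)
    expect_gte(res$pooled_p, min(res$p_t, res$p_r) - 1e-12)
    expect_lte(res$pooled_p, max(res$p_t, res$p_r) + 1e-12)
    expect_equal(res$p_one_sided, pnorm(res$z, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("p-value is monotone non-increasing in the target count", {
  for (nt in c(5, 12, 30)) {
    for (ref in list(c(3, 10), c(40, 100), c(1, 1000), c(999, 1000))) {
      p <- vapply(0:nt, function(k)
        two_proportion_ztest(k, nt, ref[1], ref[2])$p_one_sided, numeric(1))
      expect_true(all(diff(p) <= 1e-12))
    }
  }
})

test_that("swapping target and reference negates the statistic", {
  set.seed(11)
  for (rep in 1:50) {
    nt <- sample(2:40, 1); nr <- sample(2:400, 1)
    ct <- sample(0:nt, 1); cr <- sample(0:nr, 1)
    z1 <- two_proportion_ztest(ct, nt, cr, nr)$z
    z2 <- two_proportion_ztest(cr, nr, ct, nt)$z
    expect_equal(z1, -z2, tolerance = 1e-12)
  }
})

test_that("huge references converge to the one-sample normal limit", {
  n_r <- 1e9
  for (p_r in c(0.2, 0.5, 0.707)) {
    for (ct in c(10, 25, 40)) {
      n_t <- 50
      two <- two_proportion_ztest(ct, n_t, round(p_r * n_r), n_r)
      p_t <- ct / n_t
      one <- 1 - pnorm((p_t - p_r) / sqrt(p_r * (1 - p_r) / n_t))
      expect_equal(two$p_one_sided, one, tolerance = 5e-4)
    }
  }
})

test_that("DFP uses the at-least rule, so ties at the threshold set the bit", {
  prof <- bit_count_profile(c(1, 2, 1), 2)
  expect_equal(build_dfp(prof, 0.5)$bits, c(1, 1, 1))

  # a matrix of identical rows collapses to that row at any threshold
  row <- c(1, 0, 1, 1, 0)
  m <- bit_matrix(matrix(rep(row, 10), 10, byrow = TRUE))
  for (thr in c(0.1, 0.5, 1)) {
    expect_equal(build_dfp(count_bits(m), thr)$bits, row)
  }
  expect_error(build_dfp(prof, 0), "threshold")
  expect_error(build_dfp(prof, 1.5), "threshold")
})

test_that("DFP and SB-DFP match per-bit brute-force reimplementation", {
  set.seed(21)
  for (rep in 1:5) {
    m <- random_bitmatrix(500, 166, p = runif(1, 0.1, 0.6), seed = rep)
    prof <- count_bits(m)
    dfp <- build_dfp(prof, 0.5)
    manual <- vapply(seq_len(166), function(j)
      as.integer(sum(m$bits[, j]) / 500 >= 0.5), integer(1))
    expect_equal(dfp$bits, manual)

    ref <- bit_count_profile(rbinom(166, 1e5, 0.3), 1e5)
    sb <- build_sbdfp(prof, ref, 0.01)
    manual_sb <- vapply(seq_len(166), function(j) {
      as.integer(ztest_loop(prof$counts[j], 500,
                            ref$counts[j], 1e5)$p < 0.01)
    }, integer(1))
    expect_equal(sb$bits, manual_sb)
  }
})

test_that("SB-DFP of a set against itself is all-zero", {
  prof <- count_bits(random_bitmatrix(100, 64, seed = 5))
  sb <- build_sbdfp(prof, prof, 0.01)
  expect_equal(sum(sb$bits), 0)
  expect_error(build_sbdfp(prof, prof, 0), "alpha")
  expect_error(build_sbdfp(prof, prof, 1), "alpha")
})

test_that("the documented worked example drives SB-DFP bit decisions", {
  ref <- bit_count_profile(10892579, 15403690, "MACCS-166")
  hit <- bit_count_profile(268, 350, "MACCS-166")
  miss <- bit_count_profile(248, 350, "MACCS-166")
  expect_equal(build_sbdfp(hit, ref, 0.01)$bits, 1L)
  expect_equal(build_sbdfp(miss, ref, 0.01)$bits, 0L)
})

test_that("min_significant_count finds the documented boundary of 268", {
  k <- min_significant_count(350, 10892579, 15403690, 0.01)
  expect_identical(k, 268L)
  expect_lt(two_proportion_ztest(k, 350, 10892579, 15403690)$p_one_sided,
            0.01)
  expect_gte(two_proportion_ztest(k - 1, 350, 10892579,
                                  15403690)$p_one_sided, 0.01)
})

test_that("min_significant_count equals an exhaustive scan on small cases", {
  set.seed(31)
  for (rep in 1:30) {
    nt <- sample(1:30, 1); nr <- sample(1:1000, 1)
    cr <- sample(0:nr, 1); alpha <- runif(1, 0.005, 0.2)
    scan <- NA_integer_
    for (k in 0:nt) {
      if (two_proportion_ztest(k, nt, cr, nr)$p_one_sided < alpha) {
        scan <- k; break
      }
    }
    expect_identical(min_significant_count(nt, cr, nr, alpha),
                     as.integer(scan))
  }
})

test_that("min_significant_count reports unattainable thresholds as NA", {
  # a tiny target set cannot beat a near-saturated reference at tiny alpha
  expect_true(is.na(min_significant_count(2, 999, 1000, 1e-6)))
})

test_that("alpha sweep produces monotonically sparser fingerprints", {
  set.seed(41)
  tgt <- count_bits(random_bitmatrix(200, 64, p = 0.4, seed = 6))
  ref <- bit_count_profile(round(runif(64, 0.1, 0.5) * 1e6), 1e6)
  sweep <- sbdfp_alpha_sweep(tgt, ref)
  dens <- vapply(sweep, function(fp) sum(fp$bits), numeric(1))
  # smaller alpha = stricter test = no more bits set
  expect_true(all(diff(dens) <= 0))
  expect_named(sweep, c("0.1", "0.05", "0.01", "0.005", "0.001"))
})
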