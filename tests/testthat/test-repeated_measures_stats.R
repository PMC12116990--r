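test_that("Shapiro-Wilk is affine-invariant and matches an external reference", {
  set.seed(1)
  x <- rnorm(20)
  expect_equal(shapiro_wilk(x)$W, shapiro_wilk(3 * x - 7)$W, tolerance = 1e-10)
  # 12-point sample pinned against an independent reference implementation
  # (scipy.stats.shapiro): W = 0.9073352596, p = 0.1971871077
  xref <- c(2.1, 3.4, 1.9, 5.6, 4.4, 2.2, 7.8, 3.1, 4.0, 2.7, 5.1, 3.3)
  sw <- shapiro_wilk(xref)
  expect_equal(sw$W, 0.9073352596, tolerance = 1e-6)
  expect_equal(sw$p, 0.1971871077, tolerance = 1e-6)
  # strongly bimodal 50-point sample is detected
  bimod <- c(rnorm(25, -4, 0.3), rnorm(25, 4, 0.3))
  expect_lt(shapiro_wilk(bimod)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("paired comparison gates on normality and enumerates the exact Wilcoxon tail", {
  expect_identical(compare_two_timepoints(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                   list(test = "degenerate", statistic = NA_real_, p = 1,
                        degenerate = TRUE))
  # all-positive differences forced down the Wilcoxon branch:
  # exact two-sided p = 2/2^6
  base <- rep(0, 6); fol <- c(1, 2, 3, 4, 5, 6)
  res <- compare_two_timepoints(base, fol, alpha_normality = 1)
  expect_identical(res$test, "wilcoxon_signed_rank")
  expect_equal(res$p, 2 / 64)
  # brute-force sign-pattern enumeration oracle for an arbitrary n = 8 case
  d <- c(3.2, -1.1, 0.7, 2.5, 4.4, -0.3, 1.9, 2.2)
  w_plus <- function(dd) sum(rank(abs(dd))[dd > 0])
  obs <- w_plus(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  w_all <- apply(signs, 1, function(s) w_plus(abs(d) * s))
  n_w <- length(w_all)
  p_oracle <- min(1, 2 * min(mean(w_all >= obs), mean(w_all <= obs)))
  res8 <- compare_two_timepoints(rep(0, 8), d, alpha_normality = 1)
  expect_equal(res8$p, p_oracle)
  # gate behaviour: clearly normal differences use the paired t-test
  set.seed(2)
  b <- rnorm(30); f <- b + rnorm(30, 0.2)
  expect_identical(compare_two_timepoints(b, f)$test, "paired_t")
})

test_that("paired comparison holds its type-I error", {
  set.seed(33)
  rej <- vapply(seq_len(1000), function(i) {
    b <- rnorm(20); f <- b + rnorm(20)
    compare_two_timepoints(b, f)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Friedman statistic matches hand rank arithmetic and the reference implementation", {
  m <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), nrow = 3)  # rows rank (1,2,3)
  res <- friedman_test(m)
  expect_equal(res$statistic, 6)
  expect_equal(res$p, pchisq(6, 2, lower.tail = FALSE))
  # all timepoints identical: Q = 0, p = 1
  expect_equal(friedman_test(matrix(5, 4, 3))[c("statistic", "p")],
               list(statistic = 0, p = 1))
  # tie-free random data agrees with stats::friedman.test
  set.seed(6)
  r <- matrix(rnorm(27 * 5), 27)
  ref <- stats::friedman.test(r)
  mine <- friedman_test(r)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(friedman_test(matrix(1, 1, 3)), ">= 2 complete subjects")
})

test_that("Friedman test holds its type-I error at n = 27", {
  set.seed(44)
  rej <- vapply(seq_len(1000), function(i)
    friedman_test(matrix(rnorm(27 * 4), 27))$p < 0.05, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Nemenyi p-matrix is symmetric with unit diagonal and saturates on identical columns", {
  one_col <- matrix(rep(c(1, 3, 2, 5), 3), ncol = 3)
  p_same <- nemenyi_posthoc(one_col)
  expect_true(all(p_same[upper.tri(p_same)] > 0.999))
  set.seed(7)
  m <- matrix(rnorm(10 * 4), 10)
  p <- nemenyi_posthoc(m)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), rep(1, 4))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("Nemenyi detects a planted large shift against baseline", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(rnorm(27 * 4), 27)
    m[, 3] <- m[, 3] + 3
    colnames(m) <- c("0", "2", "4", "10")
    nemenyi_posthoc(m)["0", "4"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Dunnett adjustment reduces to the paired t-test at one contrast and is monotone", {
  set.seed(9)
  m <- cbind(`0` = rnorm(15), `10` = rnorm(15, 0.4))
  d <- dunnett_vs_baseline(m, "0", n_draws = 2e5, seed = 3)
  tt <- t.test(m[, "10"], m[, "0"], paired = TRUE)$p.value
  expect_equal(d$p_adjusted, tt, tolerance = 5e-3)
  # multiplicity monotonicity across 3 contrasts
  m3 <- cbind(`0` = rnorm(15), `2` = rnorm(15), `4` = rnorm(15, 1),
              `10` = rnorm(15))
  d3 <- dunnett_vs_baseline(m3, "0", n_draws = 5e4, seed = 4)
  expect_true(all(d3$p_adjusted >= d3$p_raw))
  expect_error(dunnett_vs_baseline(m3, "99"), "not found")
})

test_that("Dunnett familywise error is near nominal under the null", {
  set.seed(10)
  rej <- vapply(seq_len(400), function(i) {
    m <- matrix(rnorm(20 * 4), 20)
    colnames(m) <- c("0", "2", "4", "10")
    any(dunnett_vs_baseline(m, "0", n_draws = 2e4,
                            seed = i)$p_adjusted < 0.05)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("Benjamini-Hochberg matches hand step-up arithmetic", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # hand oracle on an unsorted vector: q_i = min_{j: p_j >= p_i} m*p_j/rank_j
  p <- c(0.30, 0.01, 0.04, 0.80, 0.02)
  ord <- order(p); m <- length(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  expect_equal(benjamini_hochberg(p)[ord], pmin(1, q_sorted))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screen_features flags planted transient effects and records all stages", {
  found <- vapply(1:5, function(s) {
    es <- effect_spec(as.list(setNames(
      rep(list(c(0, 0, -2.5, -2.5, 0)), 3), c("1", "2", "3"))))
    sim <- simulate_abundance(cohort_design(seed = 200 + s),
                              guild_spec(n_features = 40,
                                         block_sizes = rep(5, 4)),
                              es)
    scr <- screen_features(sim$table, sim$metadata, baseline = "0")
    affected <- names(sim$truth$membership)[sim$truth$membership <= 3]
    sum(scr$significant[scr$feature_id %in% affected])
  }, numeric(1))
  expect_gte(median(found), 12)   # >= 12 of the 15 planted features
  # structural checks on the result table
  sim <- simulate_abundance(cohort_design(n_subjects = 6, seed = 1),
                            guild_spec(n_features = 10, block_sizes = 5))
  scr <- screen_features(sim$table, sim$metadata, baseline = "0")
  expect_identical(nrow(scr), 10L)
  expect_true(all(scr$bh_q >= scr$screen_p | !is.finite(scr$screen_p) |
                    scr$bh_q <= 1))
  expect_error(screen_features(sim$table, sim$metadata, baseline = "0",
                               contrasts = character(0)), "empty contrast")
})

test_that("power calculation reproduces the a-priori sample-size analysis", {
  req <- required_n(effect_size_f = 0.3, alpha = 0.05, target_power = 0.85,
                    m = 4, corr_among_rm = 0.5, nonsphericity = 1)
  expect_identical(req$n, 19L)
  expect_equal(round(req$achieved_power, 2), 0.86)
  # minimality: one subject fewer misses the target
  expect_lt(rm_anova_power(18, 0.3, 0.05, 4, 0.5, 1), 0.85)
  # power strictly increases in n
  pw <- vapply(5:40, rm_anova_power, numeric(1))
  expect_true(all(diff(pw) > 0))
  # null limit: f -> 0 drives power to alpha
  expect_equal(rm_anova_power(20, 1e-9, 0.05, 4, 0.5, 1), 0.05,
               tolerance = 1e-6)
})

test_that("dose arithmetic reproduces the supplement's daily delivery", {
  expect_equal(pac_dose(20, 2, 0.05, 0.80),
               list(gp_g_per_day = 2.0, pac_g_per_day = 1.6))
  expect_equal(pac_dose(20, 1, 0.05, 0.80),
               list(gp_g_per_day = 1.0, pac_g_per_day = 0.8))
  expect_equal(pac_dose(20, 2, 0.05, 0)$pac_g_per_day, 0)
  expect_error(pac_dose(-1, 2, 0.5, 0.5), ">= 0")
})
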