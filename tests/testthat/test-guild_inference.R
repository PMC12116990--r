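test_that("prevalence filter applies the ceiling boundary and reports abundance share", {
  # 10 samples: present in 1 -> dropped, present in 2 (= ceil(0.2*10)) -> kept
  m <- matrix(0, 3, 10, dimnames = list(c("rare", "edge", "common"),
                                        paste0("s", 1:10)))
  m["rare", 1] <- 1; m["edge", 1:2] <- 1; m["common", ] <- 1
  rel <- sweep(m, 2, colSums(m), "/")
  tab <- abundance_table(rel, "relative")
  out <- filter_prevalent(tab, 0.20)
  expect_setequal(rownames(out$table), c("edge", "common"))
  expect_identical(out$report$n_dropped, 1L)

  # hand arithmetic: kept features hold 49 of 50 abundance units -> 0.98
  m2 <- matrix(c(0.50, 0.46, 0.04,
                 0.50, 0.50, 0), 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab2 <- abundance_table(m2, "relative")
  out2 <- filter_prevalent(tab2, min_prevalence = 1)   # need presence in all
  expect_setequal(rownames(out2$table), c("a", "b"))
  expect_equal(out2$report$abundance_share, 49 / 50, tolerance = 1e-12)

  expect_error(filter_prevalent(tab, 0), "min_prevalence")
  empty <- abundance_table(matrix(c(1, 0), 1, 2,
                                  dimnames = list("f", c("x", "y"))),
                           "relative", validate = FALSE)
  expect_error(filter_prevalent(empty, 1), "no feature")
})

test_that("repeated-measures correlation removes between-subject shifts", {
  subj <- rep(c("A", "B"), each = 4)
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(rm_correlation(x, x, subj), 1)
  expect_equal(rm_correlation(x, -x, subj), -1)
  # between-subject shift leaves r untouched
  x_shift <- x + c(0, 0, 0, 0, 10, 10, 10, 10)
  set.seed(4)
  y <- rnorm(8)
  expect_equal(rm_correlation(x, y, subj), rm_correlation(x_shift, y, subj))
  expect_equal(rm_correlation(x, y, subj), oracle_rm_correlation(x, y, subj))
  # single subject reduces to plain Pearson of the centered values
  set.seed(5)
  x1 <- rnorm(9); y1 <- rnorm(9)
  expect_equal(rm_correlation(x1, y1, rep("A", 9)), cor(x1, y1))
  # constant-within-subject input is an undefined correlation
  expect_error(rm_correlation(rep(1, 8), y, subj), "undefined")
})

test_that("correlation distance matrix matches element-wise brute force", {
  set.seed(8)
  md <- toy_metadata(n_subjects = 5)
  v <- matrix(abs(rnorm(4 * nrow(md))), 4,
              dimnames = list(paste0("f", 1:4), md$sample_id))
  tab <- abundance_table(sweep(v, 2, colSums(v), "/"), "relative")
  D <- correlation_distance_matrix(tab, md)
  vv <- unclass(tab)
  for (i in 1:4) for (j in 1:4) {
    expected <- if (i == j) 0 else
      1 - oracle_rm_correlation(vv[i, ], vv[j, ], md$subject_id)
    expect_equal(D[i, j], expected, tolerance = 1e-12)
  }
  expect_true(all(D >= 0 & D <= 2))
  expect_equal(D, t(D))
})

test_that("perfect co- and anti-variation give distances 0 and 2", {
  md <- toy_metadata(n_subjects = 4)
  base <- seq_len(nrow(md)) + rep(c(0, 5, 9, 2), each = 3)
  v <- rbind(f1 = base, f2 = 2 * base + 1, f3 = max(base) + 2 - base)
  colnames(v) <- md$sample_id
  tab <- abundance_table(v, "counts")
  D <- correlation_distance_matrix(tab, md)
  expect_equal(D["f1", "f2"], 0, tolerance = 1e-12)
  expect_equal(D["f1", "f3"], 2, tolerance = 1e-12)
})

test_that("zero within-subject variance features fall back to r = 0 with warning", {
  md <- toy_metadata(n_subjects = 4)
  set.seed(2)
  v <- rbind(flat = rep(1, nrow(md)), f2 = runif(nrow(md)),
             f3 = runif(nrow(md)))
  colnames(v) <- md$sample_id
  tab <- abundance_table(v, "counts", validate = FALSE)
  expect_warning(D <- correlation_distance_matrix(tab, md), "flat")
  expect_equal(unname(D["flat", c("f2", "f3")]), c(1, 1))
  expect_equal(D["flat", "flat"], 0)
})

test_that("ward tree matches a brute-force Lance-Williams oracle", {
  set.seed(13)
  X <- matrix(rnorm(5 * 3), 5)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("i", 1:5), paste0("i", 1:5))
  tr <- ward_tree(D)
  expect_equal(tr$height, oracle_ward_merge_heights(D), tolerance = 1e-10)
  # two identical items merge first
  D2 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr2 <- ward_tree(D2)
  expect_setequal(tr2$merge[1, ], c(-1, -2))
  # exchangeable distances: first-level merge heights equal
  D3 <- matrix(1, 4, 4) - diag(4)
  dimnames(D3) <- list(letters[1:4], letters[1:4])
  tr3 <- ward_tree(D3)
  expect_equal(tr3$height[1], tr3$height[2], tolerance = 1e-12)
})

test_that("permanova matches full enumeration and vegan on small problems", {
  # two groups of 2 with a huge between-group gap: exact p by enumeration
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("i", 1:4), paste0("i", 1:4))
  lab <- c("a", "a", "b", "b")
  exact <- oracle_permanova_p(D, lab)
  # exhaustive enumeration: of the C(4,2)=6 relabelings only the split and
  # its mirror reach F_obs, the minimum attainable under the add-one rule
  res <- permanova(D, lab, exact = TRUE)
  expect_equal(exact, 2 / 6)
  expect_equal(res$p, exact)
  # the sampled add-one estimator converges to the same tail probability
  res_mc <- permanova(D, lab, n_permutations = 2999, seed = 1)
  expect_equal(res_mc$p, (1 + 2999 * exact) / (1 + 2999), tolerance = 0.05)
  # pseudo-F agrees with an independent implementation
  set.seed(42)
  X2 <- matrix(rnorm(12 * 3), 12)
  D2 <- as.matrix(dist(X2))
  dimnames(D2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  lab2 <- rep(c("a", "b", "c"), each = 4)
  mine <- permanova(D2, lab2, n_permutations = 99, seed = 1)
  veg <- vegan::adonis2(as.dist(D2) ~ g, data = data.frame(g = lab2),
                        permutations = 99)
  expect_equal(mine$pseudo_F, veg$F[1], tolerance = 1e-10)
  expect_error(permanova(D2, rep("a", 12)), ">= 2 groups")
})

test_that("stratified permutations keep labels within subjects; degenerate strata give p = 1", {
  # labels constant within every stratum: no permutation can change them
  set.seed(3)
  X <- matrix(rnorm(8 * 2), 8)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
  lab <- rep(c("a", "b"), each = 4)
  strata <- rep(c("u", "v"), each = 4)   # label constant within stratum
  res <- permanova(D, lab, n_permutations = 199, seed = 2, strata = strata)
  expect_equal(res$p, 1)
})

test_that("tree cutting recovers planted blocks and respects stopping rules", {
  # two well-separated blocks of 5 -> exactly the 2 planted guilds
  set.seed(10)
  X <- rbind(matrix(rnorm(5 * 3, 0), 5), matrix(rnorm(5 * 3, 20), 5))
  D <- as.matrix(dist(X))
  ids <- paste0("f", 1:10)
  dimnames(D) <- list(ids, ids)
  part <- cut_tree_to_guilds(ward_tree(D), D, alpha = 0.05,
                             n_permutations = 999, seed = 1)
  expect_identical(length(unique(part)), 2L)
  expect_identical(length(unique(part[1:5])), 1L)
  expect_identical(length(unique(part[6:10])), 1L)

  # exchangeable D: root split not significant at 0.001 -> a single guild
  ones <- 0
  for (s in 1:5) {
    set.seed(s)
    Dn <- matrix(1, 8, 8) + matrix(rnorm(64, 0, 1e-6), 8)
    Dn <- (Dn + t(Dn)) / 2; diag(Dn) <- 0
    dimnames(Dn) <- list(paste0("f", 1:8), paste0("f", 1:8))
    p <- cut_tree_to_guilds(ward_tree(Dn), Dn, alpha = 0.001,
                            n_permutations = 999, seed = s)
    ones <- ones + (max(p) == 1)
  }
  expect_gte(ones, 3)   # majority of seeds

  # 2-item tree cannot be tested: one guild of 2
  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- cut_tree_to_guilds(ward_tree(D2), D2, seed = 1)
  expect_equal(as.integer(p2), c(1L, 1L))
})

test_that("raising alpha never decreases the number of guilds", {
  sim <- simulate_abundance(cohort_design(n_subjects = 10, seed = 17),
                            guild_spec(n_features = 30,
                                       block_sizes = c(6, 6, 6)))
  D <- correlation_distance_matrix(sim$table, sim$metadata)
  tr <- ward_tree(D)
  n_guilds <- vapply(c(0.001, 0.01, 0.05, 0.2),
                     function(a) max(cut_tree_to_guilds(tr, D, alpha = a,
                                                        n_permutations = 199,
                                                        seed = 99)),
                     numeric(1))
  expect_true(all(diff(n_guilds) >= 0))
})

test_that("guild abundances conserve totals and match hand sums", {
  tab <- toy_rel_table()
  part <- c(f1 = 1L, f2 = 1L, f3 = 2L)
  ga <- guild_abundance(tab, part)
  v <- unclass(tab)
  expect_equal(unname(unclass(ga)["guild_1", ]), unname(v["f1", ] + v["f2", ]))
  expect_equal(colSums(ga), colSums(tab))
  # singleton partition is the identity
  single <- stats::setNames(1:3, paste0("f", 1:3))
  expect_equal(unname(unclass(guild_abundance(tab, single))), unname(v))
  expect_error(guild_abundance(tab, c(f1 = 1L)), "lacks feature")
})
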