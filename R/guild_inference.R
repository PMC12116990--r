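# Guild delineation: prevalence filter, within-subject co-abundance
# correlation, Ward tree, sequential permutational-MANOVA tree cutting.

#' Keep prevalent features
#'
#' A feature is retained when it is present (abundance strictly > 0) in at
#' least `ceiling(min_prevalence * n_samples)` samples. The report records
#' how many features were kept and what share of the total summed abundance
#' they carry.
#'
#' @param table a relative-mode [abundance_table].
#' @param min_prevalence required fraction of samples, in (0, 1]; default
#'   0.20.
#' @return `list(table =, report =)`; `report` has `n_kept`, `n_dropped`
#'   and `abundance_share`.
#' @export
filter_prevalent <- function(table, min_prevalence = 0.20) {
  if (!inherits(table, "abundance_table") ||
      !identical(table_mode(table), "relative"))
    stop("filter_prevalent() expects a relative-mode abundance_table")
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]")
  need <- ceiling(min_prevalence * ncol(table))
  present <- rowSums(unclass(table) > 0)
  keep <- present >= need
  if (!any(keep)) stop("no feature passes the prevalence filter")
  tot <- sum(table)
  kept <- abundance_table(unclass(table)[keep, , drop = FALSE],
                          mode = "relative", validate = FALSE)
  list(table = kept,
       report = list(n_kept = sum(keep), n_dropped = sum(!keep),
                     min_samples = need,
                     abundance_share = if (tot > 0) sum(kept) / tot else NA_real_))
}

#' Repeated-measures (within-subject) correlation
#'
#' Correlation of the deviations from each subject's own means,
#' \deqn{r = \frac{\sum_{i,t} (x_{it}-\bar x_i)(y_{it}-\bar y_i)}
#'   {\sqrt{\sum (x_{it}-\bar x_i)^2 \sum (y_{it}-\bar y_i)^2}},}
#' which removes inter-individual level differences before asking whether
#' two variables co-vary over time. With `method = "pearson"` the plain
#' Pearson correlation across all samples is returned instead.
#'
#' @param x,y numeric vectors, one value per sample.
#' @param subjects subject id per sample.
#' @param method `"within"` (default) or `"pearson"`.
#' @return correlation in `[-1, 1]`.
#' @export
rm_correlation <- function(x, y, subjects, method = c("within", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(subjects))
    stop("x, y and subjects must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; subjects <- subjects[ok]
  if (method == "pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("correlation undefined: constant input")
    return(stats::cor(x, y))
  }
  # subjects with a single complete sample contribute zero deviation and
  # drop out of the sums automatically
  xc <- x - stats::ave(x, subjects)
  yc <- y - stats::ave(y, subjects)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined: no within-subject variance")
  max(-1, min(1, sum(xc * yc) / sqrt(sx * sy)))
}

#' Feature-feature correlation distance matrix
#'
#' Computes the repeated-measures correlation between every pair of
#' features and converts it to a correlation distance `1 - r` in `[0, 2]`.
#' Features with zero within-subject variance get `r = 0` (distance 1)
#' against every other feature, with a warning, so the matrix stays
#' complete.
#'
#' @param table a (filtered) relative-mode [abundance_table].
#' @param metadata aligned metadata (defines the subjects).
#' @param method correlation variant, `"within"` or `"pearson"`.
#' @return symmetric distance matrix with zero diagonal, features as
#'   dimnames.
#' @export
correlation_distance_matrix <- function(table, metadata,
                                        method = c("within", "pearson")) {
  method <- match.arg(method)
  al <- align_samples(table, metadata)
  v <- unclass(al$table)
  if (method == "within") {
    subj <- al$metadata$subject_id
    cen <- v - t(apply(v, 1L, function(r) stats::ave(r, subj)))
  } else {
    cen <- v - rowMeans(v)
  }
  ss <- rowSums(cen^2)
  degen <- ss == 0
  if (any(degen)) {
    warning(sprintf(
      "%d feature(s) with no within-subject variance set to r = 0: %s",
      sum(degen), paste(rownames(v)[degen], collapse = ", ")))
    cen[degen, ] <- 0
    ss[degen] <- 1   # any positive value: numerator is 0 anyway
  }
  sc <- cen / sqrt(ss)
  r <- tcrossprod(sc)
  r[r > 1] <- 1; r[r < -1] <- -1
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

#' Ward tree over a distance matrix
#'
#' Agglomerative clustering with the Ward criterion applied to squared
#' input distances (the `ward.D2` convention).
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return an [stats::hclust] tree.
#' @export
ward_tree <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  if (attr(d, "Size") < 2) stop("need >= 2 items to build a tree")
  stats::hclust(d, method = "ward.D2")
}

#' Permutational MANOVA (PERMANOVA) on a distance matrix
#'
#' One-way pseudo-F from a distance matrix:
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = ((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`.
#' Significance by label permutation with the add-one estimator
#' `p = (1 + #(F* >= F)) / (1 + n_permutations)`, so p can never be 0.
#' With `strata`, labels are shuffled only within each stratum, preserving
#' e.g. subject structure under the null.
#'
#' @param D symmetric distance matrix.
#' @param labels group label per item (>= 2 non-empty groups).
#' @param n_permutations number of random permutations.
#' @param seed integer seed for the permutations.
#' @param strata optional stratum per item restricting permutations.
#' @param exact enumerate every distinct relabeling instead of sampling
#'   (two-group designs; with `strata`, every combination of within-stratum
#'   arrangements). The identity relabeling is part of the enumeration, so
#'   the result coincides with the add-one estimator at full coverage.
#' @return `list(pseudo_F, p, n_permutations, df)`; `pseudo_F` is `Inf`
#'   when `SS_within = 0`.
#' @export
permanova <- function(D, labels, n_permutations = 9999, seed = NULL,
                      strata = NULL, exact = FALSE) {
  D <- as.matrix(D)
  N <- nrow(D)
  if (length(labels) != N) stop("labels length must match the matrix")
  labels <- as.character(labels)
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2) stop("need >= 2 groups")
  if (N < 3) stop("need >= 3 items")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  d2 <- D^2
  ss_total <- sum(d2) / (2 * N)

  f_stat <- function(lab) {
    ssw <- 0
    for (g in groups) {
      idx <- lab == g
      ng <- sum(idx)
      if (ng == 0) return(NA_real_)
      if (ng > 1) ssw <- ssw + sum(d2[idx, idx]) / (2 * ng)
    }
    if (ssw <= 0) return(Inf)
    ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }
  f_obs <- f_stat(labels)

  if (exact) {
    labs_list <- enumerate_relabelings(labels, strata)
    f_all <- vapply(labs_list, f_stat, numeric(1))
    return(list(pseudo_F = f_obs,
                p = mean(f_all >= f_obs),
                n_permutations = length(labs_list) - 1L,
                df = c(a - 1, N - a)))
  }

  perm_one <- if (is.null(strata)) {
    function() sample(labels)
  } else {
    strata <- as.character(strata)
    idx_by_s <- split(seq_len(N), strata)
    function() {
      lab <- labels
      for (ii in idx_by_s) lab[ii] <- lab[ii][sample.int(length(ii))]
      lab
    }
  }
  runner <- function() {
    f_perm <- vapply(seq_len(n_permutations),
                     function(i) f_stat(perm_one()), numeric(1))
    (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  }
  p <- if (is.null(seed)) runner() else with_stream(seed, "permanova", runner())
  list(pseudo_F = f_obs, p = p, n_permutations = n_permutations,
       df = c(a - 1, N - a))
}

# all distinct relabelings (identity included); unstratified case supports
# two groups, stratified case any labels with a product cap
enumerate_relabelings <- function(labels, strata = NULL, cap = 1e5) {
  N <- length(labels)
  if (is.null(strata)) {
    groups <- unique(labels)
    if (length(groups) != 2)
      stop("exact enumeration is implemented for two groups")
    na <- sum(labels == groups[1])
    if (choose(N, na) > cap) stop("too many relabelings to enumerate")
    combs <- utils::combn(N, na)
    lapply(seq_len(ncol(combs)), function(c2) {
      lab <- rep(groups[2], N); lab[combs[, c2]] <- groups[1]; lab
    })
  } else {
    idx_by_s <- split(seq_len(N), as.character(strata))
    per_s <- lapply(idx_by_s, function(ii) {
      perms <- unique(all_permutations(labels[ii]))
      perms
    })
    total <- prod(vapply(per_s, length, numeric(1)))
    if (total > cap) stop("too many relabelings to enumerate")
    choice <- expand.grid(lapply(per_s, seq_along), KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(choice)), function(r) {
      lab <- labels
      for (s in seq_along(idx_by_s))
        lab[idx_by_s[[s]]] <- per_s[[s]][[choice[r, s]]]
      lab
    })
  }
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(all_permutations(x[-i]), function(p) c(x[i], p)))
  out
}

# fast two-group permanova used inside the tree cut: indicator-matrix
# algebra over all permutations at once
permanova2_fast <- function(d2, in_a, n_permutations) {
  N <- nrow(d2)
  na <- sum(in_a); nb <- N - na
  ss_total <- sum(d2) / (2 * N)
  ssw_of <- function(a_ind) {
    sa <- if (na > 1) sum(d2[a_ind, a_ind]) / (2 * na) else 0
    sb <- if (nb > 1) sum(d2[!a_ind, !a_ind]) / (2 * nb) else 0
    sa + sb
  }
  f_of <- function(ssw) if (ssw <= 0) Inf else
    (ss_total - ssw) / (ssw / (N - 2))
  f_obs <- f_of(ssw_of(in_a))
  # all permutations at once: A is N x P 0/1 membership of group a
  A <- vapply(seq_len(n_permutations), function(i) {
    z <- logical(N); z[sample.int(N, na)] <- TRUE; z
  }, logical(N))
  storage.mode(A) <- "double"
  B <- 1 - A
  sa <- colSums(A * (d2 %*% A)) / (2 * na)
  sb <- colSums(B * (d2 %*% B)) / (2 * nb)
  ssw <- sa + sb
  f_perm <- ifelse(ssw <= 0, Inf, (ss_total - ssw) / (ssw / (N - 2)))
  list(pseudo_F = f_obs,
       p = (1 + sum(f_perm >= f_obs)) / (1 + n_permutations))
}

#' Cut a Ward tree into guilds by sequential PERMANOVA
#'
#' Starting from the root, each internal node's two clades are compared by
#' PERMANOVA on the corresponding submatrix of the feature distance matrix.
#' If the clades differ significantly (`p <= alpha`) the descent recurses
#' into both children; otherwise all members of the node form one guild.
#' Nodes with fewer than 3 members cannot be tested and stop the descent;
#' leaves reached by recursion become singleton guilds. Guild labels are
#' numbered in tree-traversal order.
#'
#' @param tree [stats::hclust] tree from [ward_tree].
#' @param D the distance matrix the tree was built from.
#' @param alpha significance level for a split (default 0.001).
#' @param n_permutations permutations per node test (default 9999).
#' @param seed integer seed; each node tests with its own RNG stream
#'   derived from `(seed, node id)` so results do not depend on traversal
#'   order.
#' @return named integer vector mapping feature id to guild label, plus a
#'   `"tests"` attribute (data.frame of node, size, pseudo_F, p, split).
#' @export
cut_tree_to_guilds <- function(tree, D, alpha = 0.001,
                               n_permutations = 9999, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(tree$order) != n) stop("tree and D disagree on the item count")
  ids <- tree$labels
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d2 <- D^2

  members <- function(node) {
    # node > 0: merge row; node < 0: leaf -node
    if (node < 0) return(-node)
    unlist(lapply(tree$merge[node, ], members))
  }
  mem_cache <- lapply(seq_len(nrow(tree$merge)), members)

  labels <- integer(n)
  next_label <- 0L
  tests <- list()

  assign_guild <- function(idx) {
    next_label <<- next_label + 1L
    labels[idx] <<- next_label
  }

  descend <- function(node) {
    if (node < 0) { assign_guild(-node); return(invisible()) }
    idx <- mem_cache[[node]]
    if (length(idx) < 3) { assign_guild(idx); return(invisible()) }
    kids <- tree$merge[node, ]
    left <- if (kids[1] < 0) -kids[1] else mem_cache[[kids[1]]]
    in_a <- idx %in% left
    res <- with_stream(stream_seed(seed, paste0("node", node)), "cut",
                       permanova2_fast(d2[idx, idx, drop = FALSE], in_a,
                                       n_permutations))
    split <- res$p <= alpha
    tests[[length(tests) + 1L]] <<- data.frame(
      node = node, size = length(idx), pseudo_F = res$pseudo_F,
      p = res$p, split = split)
    if (split) {
      descend(kids[1]); descend(kids[2])
    } else assign_guild(idx)
    invisible()
  }
  descend(nrow(tree$merge))

  out <- labels
  names(out) <- ids
  attr(out, "tests") <- do.call(rbind, tests)
  attr(out, "alpha") <- alpha
  attr(out, "n_permutations") <- n_permutations
  out
}

#' Aggregate feature abundances into guild abundances
#'
#' Per-sample sum of member relative abundances per guild; column totals
#' are conserved.
#'
#' @param table [abundance_table] whose features the partition covers.
#' @param partition named vector mapping feature id to guild label.
#' @return guilds x samples [abundance_table] (same mode as the input),
#'   guild ids `"guild_<label>"`.
#' @export
guild_abundance <- function(table, partition) {
  miss <- setdiff(rownames(table), names(partition))
  if (length(miss))
    stop("partition lacks feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  g <- partition[rownames(table)]
  agg <- rowsum(unclass(table), group = g, reorder = TRUE)
  rownames(agg) <- paste0("guild_", rownames(agg))
  abundance_table(agg, mode = table_mode(table), validate = FALSE)
}
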