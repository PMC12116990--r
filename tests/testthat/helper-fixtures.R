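# Fixtures are built in code; nothing is read from disk.

# tiny features x samples relative table
toy_rel_table <- function() {
  m <- matrix(c(0.5, 0.3, 0.2,
                0.1, 0.6, 0.3,
                0.25, 0.25, 0.5), nrow = 3,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  m <- apply(m, 2, function(col) col / sum(col))
  abundance_table(m, mode = "relative")
}

toy_metadata <- function(n_subjects = 4, timepoints = c("-5", "0", "2")) {
  grid <- expand.grid(timepoint = timepoints,
                      subject_id = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  as_sample_metadata(data.frame(
    sample_id = paste0(grid$subject_id, "_d", grid$timepoint),
    subject_id = grid$subject_id,
    timepoint = grid$timepoint,
    sex = rep(c("F", "M"), length.out = nrow(grid)),
    stringsAsFactors = FALSE))
}

# brute-force repeated-measures correlation by explicit per-subject centering
oracle_rm_correlation <- function(x, y, subjects) {
  xs <- split(x, subjects); ys <- split(y, subjects)
  xc <- unlist(lapply(xs, function(v) v - mean(v)))
  yc <- unlist(lapply(ys, function(v) v - mean(v)))
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# brute-force Ward.D2 agglomeration via the Lance-Williams update
oracle_ward_merge_heights <- function(D) {
  D <- as.matrix(D)^2      # work on squared distances
  n <- nrow(D)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[a]; j <- active[b]
      if (D[i, j] < bestv) { bestv <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# exhaustive two-group permanova p-value over all label assignments
oracle_permanova_p <- function(D, labels) {
  D <- as.matrix(D); d2 <- D^2; N <- nrow(D)
  groups <- unique(labels)
  f_of <- function(lab) {
    ssw <- 0
    for (g in groups) {
      idx <- lab == g; ng <- sum(idx)
      if (ng > 1) ssw <- ssw + sum(d2[idx, idx]) / (2 * ng)
    }
    ss_t <- sum(d2) / (2 * N)
    if (ssw <= 0) return(Inf)
    ((ss_t - ssw) / (length(groups) - 1)) / (ssw / (N - length(groups)))
  }
  f_obs <- f_of(labels)
  na <- sum(labels == groups[1])
  combs <- utils::combn(N, na)
  f_all <- apply(combs, 2, function(ii) {
    lab <- rep(groups[2], N); lab[ii] <- groups[1]; f_of(lab)
  })
  mean(f_all >= f_obs)
}
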