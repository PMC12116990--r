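# Sample-level distances, PCoA, covariate-adjusted PCoA and
# subject-stratified PERMANOVA.

#' Between-sample distance matrix
#'
#' `bray_curtis` and `jaccard` (presence/absence, presence = abundance
#' strictly > 0) follow the usual community-ecology definitions;
#' `euclidean_z` is the Euclidean distance after z-scoring each feature
#' across samples (zero-variance features dropped with a warning), the
#' metric commonly used for protein or metabolite profiles.
#'
#' @param table features x samples matrix or [abundance_table]
#'   (relative-mode required for `bray_curtis` / `jaccard`).
#' @param metric `"bray_curtis"`, `"jaccard"` or `"euclidean_z"`.
#' @return symmetric samples x samples distance matrix.
#' @export
sample_distance <- function(table,
                            metric = c("bray_curtis", "jaccard",
                                       "euclidean_z")) {
  metric <- match.arg(metric)
  v <- unclass(table)
  samp <- t(v)   # vegan expects samples in rows
  d <- switch(metric,
    bray_curtis = {
      zero <- rowSums(samp) == 0
      if (sum(zero) >= 2)
        warning("all-zero sample pair(s) under bray_curtis set to distance 0")
      dd <- as.matrix(vegan::vegdist(samp, method = "bray"))
      dd[is.nan(dd)] <- 0
      dd
    },
    jaccard = as.matrix(vegan::vegdist(samp, method = "jaccard",
                                       binary = TRUE)),
    euclidean_z = {
      sds <- apply(v, 1L, stats::sd)
      if (any(sds == 0)) {
        warning(sprintf("dropping %d zero-variance feature(s) before z-scoring",
                        sum(sds == 0)))
        v <- v[sds > 0, , drop = FALSE]
      }
      z <- t(scale(t(v)))
      as.matrix(stats::dist(t(z)))
    })
  diag(d) <- 0
  dimnames(d) <- list(colnames(v), colnames(v))
  d
}

# Gower-centered kernel G = -1/2 C d^2 C
gower_center <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  -0.5 * C %*% (D^2) %*% C
}

eig_to_ordination <- function(G, sample_ids, adjustment = "none") {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  dimnames(coords) <- list(sample_ids,
                           if (ncol(coords))
                             paste0("Axis", seq_len(ncol(coords))))
  tot_pos <- sum(pmax(e$values, 0))
  structure(list(sample_ids = sample_ids,
                 coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = if (tot_pos > 0)
                   pmax(e$values, 0) / tot_pos else rep(0, length(e$values)),
                 negative_eigenvalues = sum(e$values < -tol),
                 adjustment = adjustment),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d retained axes (adjustment: %s)\n",
              length(x$sample_ids), ncol(x$coordinates), x$adjustment))
  cat("first axes explain:",
      paste0(round(100 * utils::head(x$proportion_explained, 3), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower-centers the squared distances and eigendecomposes; coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Axes with negative eigenvalues are reported but discarded.
#'
#' @param D samples x samples distance matrix.
#' @return an `ordination_result` (coordinates, eigenvalues, proportion
#'   explained).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need >= 3 samples")
  eig_to_ordination(gower_center(D), colnames(D), adjustment = "none")
}

#' Covariate-adjusted PCoA (aPCoA)
#'
#' Projects the covariate (by default subject identity) out of the
#' Gower-centered kernel before eigendecomposition:
#' `E = (I - H) G (I - H)` with `H` the hat matrix of the covariate
#' indicator design (with intercept). Removes inter-subject variation so
#' that within-subject (e.g. timepoint) structure becomes visible.
#'
#' @param D samples x samples distance matrix.
#' @param metadata aligned metadata.
#' @param covariate metadata column to adjust for (default `subject_id`).
#' @return an `ordination_result`; coordinates are orthogonal to the
#'   covariate indicator space.
#' @export
adjusted_pcoa <- function(D, metadata, covariate = "subject_id") {
  D <- as.matrix(D)
  if (!identical(colnames(D), metadata$sample_id))
    metadata <- metadata[match(colnames(D), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id)) stop("metadata does not cover all samples")
  f <- factor(metadata[[covariate]])
  n <- nrow(D)
  if (nlevels(f) >= n)
    stop("covariate has as many levels as samples: nothing left to ordinate")
  # a single-level covariate reduces to the intercept, i.e. plain PCoA
  X <- if (nlevels(f) < 2) matrix(1, n, 1) else stats::model.matrix(~f)
  H <- X %*% solve(crossprod(X), t(X))
  IH <- diag(n) - H
  E <- IH %*% gower_center(D) %*% IH
  eig_to_ordination(E, colnames(D), adjustment = covariate)
}

#' Subject-stratified PERMANOVA across timepoints
#'
#' Runs [permanova] on a sample distance matrix with the chosen factor as
#' grouping and permutations restricted to within-stratum (by default
#' within-subject) relabelings, the appropriate null for repeated-measures
#' designs. Subjects contributing fewer than 2 samples to the tested
#' contrast are dropped with a warning.
#'
#' @param D samples x samples distance matrix.
#' @param metadata aligned metadata.
#' @param factor_col metadata column defining groups (default timepoint).
#' @param strata_col metadata column defining permutation strata (default
#'   subject).
#' @param levels optional: restrict to these factor levels (e.g. a day
#'   pair, mirroring pairwise day-contrast tables).
#' @param n_permutations,seed,exact passed to [permanova].
#' @return `list(pseudo_F, p, n_permutations, df, n_samples)`.
#' @export
stratified_permanova <- function(D, metadata, factor_col = "timepoint",
                                 strata_col = "subject_id", levels = NULL,
                                 n_permutations = 9999, seed = 1,
                                 exact = FALSE) {
  D <- as.matrix(D)
  md <- metadata[match(colnames(D), metadata$sample_id), , drop = FALSE]
  fac <- as.character(md[[factor_col]])
  keep <- rep(TRUE, nrow(md))
  if (!is.null(levels)) keep <- fac %in% as.character(levels)
  strat <- as.character(md[[strata_col]])
  tab <- table(strat[keep])
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning(sprintf("dropping %d stratum/strata with a single sample", length(small)))
    keep <- keep & !strat %in% small
  }
  if (sum(keep) < 3) stop("fewer than 3 samples left for the contrast")
  res <- permanova(D[keep, keep, drop = FALSE], fac[keep],
                   n_permutations = n_permutations, seed = seed,
                   strata = strat[keep], exact = exact)
  res$n_samples <- sum(keep)
  res
}

#' Pairwise day-contrast stratified PERMANOVAs
#'
#' Convenience wrapper running [stratified_permanova] for each listed
#' timepoint against the baseline, each on the sample subset of the two
#' days; raw p-values per pair are reported (BH across pairs available via
#' `adjust`).
#'
#' @param D samples x samples distance matrix.
#' @param metadata aligned metadata.
#' @param baseline baseline timepoint label.
#' @param days timepoints to contrast against the baseline.
#' @param adjust apply BH across the day-pairs (default FALSE).
#' @inheritParams stratified_permanova
#' @return data.frame with `contrast`, `pseudo_F`, `p` (and `q` when
#'   `adjust`).
#' @export
pairwise_stratified_permanova <- function(D, metadata, baseline = "0",
                                          days = NULL,
                                          n_permutations = 9999, seed = 1,
                                          adjust = FALSE) {
  tps <- unique(as.character(metadata$timepoint))
  if (is.null(days)) days <- setdiff(tps, baseline)
  rows <- lapply(days, function(d) {
    r <- stratified_permanova(D, metadata, levels = c(baseline, d),
                              n_permutations = n_permutations,
                              seed = stream_seed(seed, paste0("pair", d)))
    data.frame(contrast = paste0(baseline, " vs ", d),
               pseudo_F = r$pseudo_F, p = r$p, n_samples = r$n_samples,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- benjamini_hochberg(out$p)
  rownames(out) <- NULL
  out
}
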