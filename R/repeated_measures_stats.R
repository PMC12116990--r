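# Normality-gated paired tests, Friedman/Nemenyi, Dunnett-vs-baseline,
# Benjamini-Hochberg screening, and the repeated-measures ANOVA power
# calculation.

#' Shapiro-Wilk normality test
#'
#' Royston's (AS R94) approximation of the Shapiro-Wilk W statistic and
#' p-value, for 3 <= n <= 5000.
#'
#' @param values numeric vector.
#' @return `list(W, p)`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("shapiro_wilk needs 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant input: W undefined")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Normality-gated paired two-timepoint comparison
#'
#' Runs Shapiro-Wilk on the paired differences; if the differences look
#' normal (p >= `alpha_normality`) a two-sided paired t-test is used,
#' otherwise a two-sided Wilcoxon signed-rank test (exact null distribution
#' for n <= 25 after dropping zero differences, normal approximation with
#' continuity correction above).
#'
#' @param baseline,followup paired numeric vectors (>= 3 complete pairs).
#' @param alpha_normality gate level for the normality test (default 0.05).
#' @return `list(test, statistic, p, degenerate)`; `degenerate = TRUE` with
#'   `p = 1` when all differences are zero.
#' @export
compare_two_timepoints <- function(baseline, followup,
                                   alpha_normality = 0.05) {
  ok <- stats::complete.cases(baseline, followup)
  d <- followup[ok] - baseline[ok]
  if (length(d) < 3) stop("need >= 3 complete pairs")
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                degenerate = TRUE))
  sw_p <- if (stats::sd(d) == 0) 0 else shapiro_wilk(d)$p
  if (sw_p >= alpha_normality) {
    tt <- stats::t.test(d)
    list(test = "paired_t", statistic = unname(tt$statistic), p = tt$p.value,
         degenerate = FALSE)
  } else {
    dz <- d[d != 0]   # zero differences dropped (no Pratt correction)
    n <- length(dz)
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = n <= 25, correct = TRUE))
    list(test = "wilcoxon_signed_rank", statistic = unname(wt$statistic),
         p = wt$p.value, degenerate = FALSE)
  }
}

#' Friedman rank test for repeated measures
#'
#' Within-subject mid-ranks; the tie-corrected statistic
#' \deqn{Q = (k-1) \sum_j (R_j - n(k+1)/2)^2 / \sum_{ij} (r_{ij}-(k+1)/2)^2}
#' is referred to a chi-square distribution with k-1 degrees of freedom.
#' Rows with missing cells are dropped (complete-case).
#'
#' @param block_matrix subjects x timepoints numeric matrix.
#' @return `list(statistic, df, p, n)`; all-constant rows give `Q = 0`,
#'   `p = 1`.
#' @export
friedman_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 3) stop("need >= 3 timepoints")
  if (n < 2) stop("need >= 2 complete subjects")
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum((r - (k + 1) / 2)^2)
  if (den == 0)
    return(list(statistic = 0, df = k - 1L, p = 1, n = n))
  Q <- num / den
  list(statistic = Q, df = k - 1L,
       p = stats::pchisq(Q, k - 1, lower.tail = FALSE), n = n)
}

#' Nemenyi post-hoc test after Friedman
#'
#' For each pair of timepoints the standardized mean-rank difference is
#' compared to the studentized range distribution (q/sqrt(2) convention,
#' k groups, infinite df).
#'
#' @param block_matrix subjects x timepoints numeric matrix.
#' @return symmetric matrix of pairwise p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 3) stop("need >= 3 timepoints")
  if (n < 2) stop("need >= 2 complete subjects")
  r <- t(apply(m, 1L, rank))
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (12 * n))
  p <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    stat <- abs(rbar[i] - rbar[j]) / se
    pv <- stats::ptukey(stat * sqrt(2), nmeans = k, df = Inf,
                        lower.tail = FALSE)
    p[i, j] <- p[j, i] <- pv
  }
  p
}

#' Dunnett-style many-to-one comparisons against a baseline timepoint
#'
#' Each non-baseline timepoint is compared to the baseline by a paired
#' t-statistic; familywise-adjusted p-values come from the equicorrelated
#' (rho = 1/2) multivariate t reference distribution, integrated by seeded
#' Monte Carlo.
#'
#' @param block_matrix subjects x timepoints numeric matrix (complete-case).
#' @param baseline baseline timepoint (column name).
#' @param n_draws Monte Carlo draws (default 1e5).
#' @param seed integer seed for the draws.
#' @return data.frame with `timepoint`, `t`, `p_raw`, `p_adjusted`.
#' @export
dunnett_vs_baseline <- function(block_matrix, baseline, n_draws = 1e5,
                                seed = 1) {
  m <- as.matrix(block_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!baseline %in% colnames(m))
    stop("baseline timepoint '", baseline, "' not found")
  others <- setdiff(colnames(m), baseline)
  if (!length(others)) stop("no non-baseline timepoints")
  n <- nrow(m)
  if (n < 3) stop("need >= 3 complete subjects")
  df <- n - 1
  tv <- vapply(others, function(tp) {
    d <- m[, tp] - m[, baseline]
    if (stats::sd(d) == 0) return(0)
    mean(d) / (stats::sd(d) / sqrt(n))
  }, numeric(1))
  kc <- length(others)
  maxT <- with_stream(seed, "dunnett", {
    z0 <- stats::rnorm(n_draws)
    v <- sqrt(stats::rchisq(n_draws, df) / df)
    mx <- rep(0, n_draws)
    for (j in seq_len(kc)) {
      tj <- abs(sqrt(0.5) * z0 + sqrt(0.5) * stats::rnorm(n_draws)) / v
      mx <- pmax(mx, tj)
    }
    mx
  })
  p_raw <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  p_adj <- vapply(abs(tv), function(t0) mean(maxT >= t0), numeric(1))
  # the familywise-adjusted p can never undercut the raw p; guards against
  # Monte Carlo jitter in the k = 1 reduction
  data.frame(timepoint = others,
             t = unname(tv),
             p_raw = p_raw,
             p_adjusted = pmax(p_adj, p_raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR-adjusted p-values with monotone enforcement.
#' Thresholding (e.g. q <= 0.25) is the caller's job.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# repeated-measures one-way ANOVA (subject as block) on a complete
# subjects x timepoints matrix; classical two-way-without-replication F
rm_anova_f <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ss_time <- n * sum((colMeans(m) - gm)^2)
  ss_subj <- k * sum((rowMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  if (ms_err <= 0) return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  f <- (ss_time / df1) / ms_err
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Screen features for a timepoint effect with BH control and post-hocs
#'
#' For every feature (row of the table): a repeated-measures one-way ANOVA
#' (subject as block; set `block_subject = FALSE` for the plain one-way
#' ANOVA) gives the screening p-value; BH is applied across features; for
#' features passing `q <= q_threshold` the Friedman test with Nemenyi
#' pairwise post-hocs (and optionally Dunnett vs baseline) localizes the
#' affected timepoints.
#'
#' @param table features x samples matrix or [abundance_table].
#' @param metadata aligned metadata defining subject and timepoint.
#' @param baseline baseline timepoint label for the post-hoc contrasts.
#' @param contrasts timepoint labels to compare against the baseline;
#'   default all non-baseline timepoints.
#' @param q_threshold BH threshold gating the post-hocs (default 0.25).
#' @param posthoc `"nemenyi"`, `"dunnett"` or `"both"`.
#' @param block_subject block the screening ANOVA on subject (default TRUE).
#' @param seed seed for the Dunnett Monte Carlo.
#' @return data.frame (one row per feature): `feature_id`,
#'   `screen_statistic`, `screen_p`, `bh_q`, `significant`
#'   (q <= threshold), `n_complete`, `insufficient` flag, plus one
#'   `nemenyi_p_<tp>` / `dunnett_p_<tp>` column per requested contrast.
#' @export
screen_features <- function(table, metadata, baseline = "0",
                            contrasts = NULL, q_threshold = 0.25,
                            posthoc = c("nemenyi", "dunnett", "both"),
                            block_subject = TRUE, seed = 1) {
  posthoc <- match.arg(posthoc)
  al <- align_samples(table, metadata)
  v <- unclass(al$table)
  md <- al$metadata
  tps <- levels(md$timepoint)[levels(md$timepoint) %in%
                                unique(as.character(md$timepoint))]
  if (!baseline %in% tps) stop("baseline timepoint '", baseline, "' absent")
  if (is.null(contrasts)) contrasts <- setdiff(tps, baseline)
  if (!length(contrasts)) stop("empty contrast plan")
  if (!all(contrasts %in% tps))
    stop("unknown contrast timepoint(s): ",
         paste(setdiff(contrasts, tps), collapse = ", "))

  subj <- unique(md$subject_id)
  cell <- matrix(NA_integer_, length(subj), length(tps),
                 dimnames = list(subj, tps))
  idx <- cbind(match(md$subject_id, subj), match(as.character(md$timepoint), tps))
  cell[idx] <- seq_len(nrow(md))

  block_of <- function(feature_row) {
    m <- matrix(NA_real_, length(subj), length(tps),
                dimnames = list(subj, tps))
    m[!is.na(cell)] <- feature_row[cell[!is.na(cell)]]
    m[stats::complete.cases(m), , drop = FALSE]
  }

  nf <- nrow(v)
  stat <- p <- rep(NA_real_, nf)
  ncomp <- integer(nf)
  for (i in seq_len(nf)) {
    m <- block_of(v[i, ])
    ncomp[i] <- nrow(m)
    if (nrow(m) < 2) next
    if (block_subject) {
      r <- rm_anova_f(m)
    } else {
      grp <- factor(rep(colnames(m), each = nrow(m)))
      av <- stats::oneway.test(as.vector(m) ~ grp, var.equal = TRUE)
      r <- list(F = unname(av$statistic), p = av$p.value)
    }
    stat[i] <- r$F; p[i] <- r$p
  }
  insufficient <- is.na(p)
  q <- rep(NA_real_, nf)
  q[!insufficient] <- benjamini_hochberg(p[!insufficient])
  sig <- !insufficient & q <= q_threshold

  res <- data.frame(feature_id = rownames(v), screen_statistic = stat,
                    screen_p = p, bh_q = q, significant = sig,
                    n_complete = ncomp, insufficient = insufficient,
                    stringsAsFactors = FALSE)
  if (posthoc %in% c("nemenyi", "both"))
    for (tp in contrasts) res[[paste0("nemenyi_p_", tp)]] <- NA_real_
  if (posthoc %in% c("dunnett", "both"))
    for (tp in contrasts) res[[paste0("dunnett_p_", tp)]] <- NA_real_

  for (i in which(sig)) {
    m <- block_of(v[i, ])
    if (posthoc %in% c("nemenyi", "both")) {
      np <- nemenyi_posthoc(m)
      for (tp in contrasts)
        res[i, paste0("nemenyi_p_", tp)] <- np[baseline, tp]
    }
    if (posthoc %in% c("dunnett", "both")) {
      dp <- dunnett_vs_baseline(m, baseline,
                                seed = stream_seed(seed, res$feature_id[i]))
      for (tp in contrasts)
        res[i, paste0("dunnett_p_", tp)] <-
          dp$p_adjusted[dp$timepoint == tp]
    }
  }
  rownames(res) <- NULL
  res
}

#' Power of the repeated-measures within-factors ANOVA F test
#'
#' G*Power conventions: noncentrality `lambda = f^2 * n * m * eps /
#' (1 - rho)`, numerator df `(m-1)*eps`, denominator df `(n-1)*(m-1)*eps`;
#' power is the upper tail of the noncentral F beyond the central-F
#' critical value at `alpha`.
#'
#' @param n number of subjects.
#' @param effect_size_f Cohen's f (default 0.3).
#' @param alpha type-I level (default 0.05).
#' @param m number of repeated measurements.
#' @param corr_among_rm correlation among repeated measures (rho).
#' @param nonsphericity nonsphericity correction epsilon in (0, 1].
#' @return power in (0, 1).
#' @export
rm_anova_power <- function(n, effect_size_f = 0.3, alpha = 0.05, m = 4,
                           corr_among_rm = 0.5, nonsphericity = 1) {
  if (effect_size_f <= 0) stop("effect_size_f must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 2) stop("m must be >= 2")
  if (corr_among_rm < 0 || corr_among_rm >= 1) stop("rho must be in [0, 1)")
  if (nonsphericity <= 0 || nonsphericity > 1) stop("epsilon must be in (0, 1]")
  if (n < 2) stop("n must be >= 2")
  lambda <- effect_size_f^2 * n * m * nonsphericity / (1 - corr_among_rm)
  df1 <- (m - 1) * nonsphericity
  df2 <- (n - 1) * (m - 1) * nonsphericity
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' @inheritParams rm_anova_power
#' @param target_power required power (default 0.85).
#' @param n_max search bound.
#' @return `list(n, achieved_power)`.
#' @export
required_n <- function(effect_size_f = 0.3, alpha = 0.05,
                       target_power = 0.85, m = 4, corr_among_rm = 0.5,
                       nonsphericity = 1, n_max = 10000) {
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must be in (0, 1)")
  for (n in 2:n_max) {
    pw <- rm_anova_power(n, effect_size_f, alpha, m, corr_among_rm,
                         nonsphericity)
    if (pw >= target_power) return(list(n = n, achieved_power = pw))
  }
  stop("no n <= n_max reaches the target power")
}

#' Polyphenol / proanthocyanidin dose arithmetic
#'
#' Daily grape-polyphenol (GP) and proanthocyanidin (PAC) delivery from a
#' protein-matrix supplement: `gp = dose_mass * doses_per_day * gp_fraction`
#' and `pac = gp * pac_fraction`.
#'
#' @param dose_mass_g mass of one dose in grams.
#' @param doses_per_day number of doses per day.
#' @param gp_fraction mass fraction of GPs in the supplement, in `[0, 1]`.
#' @param pac_fraction fraction of GPs that are PACs, in `[0, 1]`.
#' @return `list(gp_g_per_day, pac_g_per_day)`.
#' @export
pac_dose <- function(dose_mass_g, doses_per_day, gp_fraction, pac_fraction) {
  if (dose_mass_g < 0) stop("dose mass must be >= 0")
  if (doses_per_day < 0) stop("doses_per_day must be >= 0")
  if (gp_fraction < 0 || gp_fraction > 1 ||
      pac_fraction < 0 || pac_fraction > 1)
    stop("fractions must lie in [0, 1]")
  gp <- dose_mass_g * doses_per_day * gp_fraction
  list(gp_g_per_day = gp, pac_g_per_day = gp * pac_fraction)
}
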