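# Seeded synthetic longitudinal cohorts with planted guild structure.
#
# One global seed feeds a named RNG stream per component (abundance,
# metabolites, outcomes) so adding a component never perturbs another's
# draws.

#' Cohort design for the synthetic generator
#'
#' Defaults mirror a 27-subject cohort sampled at study days -5, 0, 2, 4
#' and 10, with 16 female and 11 male participants.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param timepoints ordered vector of timepoint labels.
#' @param n_female number of female subjects (the rest are male); defaults
#'   to the 16:11 F:M ratio scaled to `n_subjects`.
#' @param seed integer seed; fully determines all draws.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_subjects = 27,
                          timepoints = c(-5, 0, 2, 4, 10),
                          n_female = round(n_subjects * 16 / 27), seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (length(timepoints) < 2) stop("need >= 2 timepoints")
  if (anyDuplicated(timepoints)) stop("duplicate timepoints")
  if (n_female < 0 || n_female > n_subjects) stop("invalid n_female")
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = as.character(timepoints),
                 n_female = as.integer(n_female),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Guild block structure for the synthetic generator
#'
#' Features are organised into co-abundant blocks sharing a latent
#' per-sample factor; features not covered by `block_sizes` are singleton
#' background features. On the log scale, feature g of block k in sample
#' (i,t) is
#' `mu_g + u_{g,i} + sqrt(rho) * z_{k,i,t} * feature_sd +
#'  sqrt(1-rho) * e_{g,i,t} * feature_sd + delta_k(t)`,
#' with `u_{g,i} ~ N(0, subject_sd^2)` a feature-specific subject
#' fingerprint (so same-subject samples cluster in Bray-Curtis space), plus
#' a whole-sample intercept with sd `sample_sd` (absorbed by closure).
#'
#' @param n_features total number of features.
#' @param block_sizes sizes of the planted guild blocks (sum <= n_features).
#' @param within_guild_corr target latent within-block correlation in (0,1).
#' @param subject_sd,sample_sd,feature_sd log-scale standard deviations.
#' @return a `guild_spec` list.
#' @export
guild_spec <- function(n_features = 120, block_sizes = rep(8L, 10L),
                       within_guild_corr = 0.7,
                       subject_sd = 1, sample_sd = 0.3, feature_sd = 1) {
  if (sum(block_sizes) > n_features)
    stop("block_sizes sum exceeds n_features")
  if (any(block_sizes < 1)) stop("block sizes must be positive")
  if (within_guild_corr <= 0 || within_guild_corr >= 1)
    stop("within_guild_corr must be in (0, 1)")
  if (feature_sd <= 0) stop("feature_sd must be > 0")
  structure(list(n_features = as.integer(n_features),
                 block_sizes = as.integer(block_sizes),
                 within_guild_corr = within_guild_corr,
                 subject_sd = subject_sd, sample_sd = sample_sd,
                 feature_sd = feature_sd),
            class = "guild_spec")
}

#' Treatment effects on planted guilds
#'
#' Each affected guild gets a per-timepoint log-fold-change vector; the
#' baseline timepoint's entry must be 0. The default emulates a transient
#' suppression at days 2 and 4 that reverts by day 10.
#'
#' @param affected named list: names are guild (block) indices, values
#'   per-timepoint log-fold-change vectors.
#' @param timepoints the design's timepoint labels (for length checks).
#' @param baseline baseline timepoint label whose effect must be 0.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(affected = list(), timepoints = c(-5, 0, 2, 4, 10),
                        baseline = "0") {
  timepoints <- as.character(timepoints)
  b <- match(baseline, timepoints)
  if (is.na(b)) stop("baseline timepoint not among timepoints")
  for (nm in names(affected)) {
    v <- affected[[nm]]
    if (length(v) != length(timepoints))
      stop("effect vector for guild ", nm, " has length ", length(v),
           ", expected ", length(timepoints))
    if (v[b] != 0)
      stop("baseline effect must be 0 for guild ", nm)
  }
  structure(list(affected = affected, timepoints = timepoints,
                 baseline = baseline),
            class = "effect_spec")
}

#' Metabolite coupling specification
#'
#' Analytes are linear in the arcsine square-root (AST) transformed relative
#' abundance of one target guild, with a subject random intercept and
#' residual noise; negative slopes encode "guild down, metabolite up".
#'
#' @param analytes data.frame with columns `name`, `intercept`, `slope`,
#'   `subject_sd`, `residual_sd`.
#' @param target_guild planted guild (block) index the slopes act on.
#' @return a `metabolite_spec` list.
#' @export
metabolite_spec <- function(analytes, target_guild = 1L) {
  req <- c("name", "intercept", "slope", "subject_sd", "residual_sd")
  miss <- setdiff(req, colnames(analytes))
  if (length(miss)) stop("analytes lacks column(s): ", paste(miss, collapse = ", "))
  if (any(analytes$residual_sd <= 0)) stop("residual_sd must be > 0")
  if (anyDuplicated(analytes$name)) stop("duplicate analyte names")
  structure(list(analytes = analytes, target_guild = as.integer(target_guild)),
            class = "metabolite_spec")
}

# deterministic per-component seed derived from a base seed and a label;
# stays below 2^31 so it is a valid R integer seed
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

#' Simulate a longitudinal compositional abundance table
#'
#' Draws log-normal latent abundances with planted co-abundance blocks,
#' feature-specific subject effects and optional transient treatment
#' effects, then closes each sample to relative abundance. The same seed
#' reproduces the output bit-identically.
#'
#' @param design a [cohort_design].
#' @param gspec a [guild_spec].
#' @param espec an [effect_spec] or `NULL` for no treatment effect.
#' @param mode `"relative"` (default) or `"counts"`; counts are Poisson
#'   draws at `depth` reads per sample.
#' @param depth sequencing depth used when `mode = "counts"`.
#' @return `list(table, metadata, truth)` where `truth` holds the planted
#'   guild membership (`membership`, a named integer vector; background
#'   features are singleton guilds), effect vectors and per-feature subject
#'   intercepts.
#' @export
simulate_abundance <- function(design, gspec = guild_spec(), espec = NULL,
                               mode = c("relative", "counts"), depth = 1e5) {
  mode <- match.arg(mode)
  if (!inherits(design, "cohort_design")) stop("`design` must be a cohort_design")
  if (!inherits(gspec, "guild_spec")) stop("`gspec` must be a guild_spec")
  tps <- design$timepoints
  if (!is.null(espec)) {
    if (!inherits(espec, "effect_spec")) stop("`espec` must be an effect_spec")
    if (!identical(espec$timepoints, tps))
      stop("effect_spec timepoints do not match the design")
  }
  p <- gspec$n_features
  n_blocks <- length(gspec$block_sizes)
  # block id per feature; background features get fresh singleton ids
  blk <- rep(seq_len(n_blocks), gspec$block_sizes)
  n_bg <- p - length(blk)
  membership <- c(blk, if (n_bg > 0) n_blocks + seq_len(n_bg))
  feature_ids <- sprintf("f%03d", seq_len(p))
  names(membership) <- feature_ids

  subj <- sprintf("S%02d", seq_len(design$n_subjects))
  grid <- expand.grid(timepoint = tps, subject_id = subj,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("subject_id", "timepoint")]
  grid$sample_id <- paste0(grid$subject_id, "_d", grid$timepoint)
  n_samp <- nrow(grid)

  rho <- gspec$within_guild_corr
  dlt <- matrix(0, nrow = max(membership), ncol = length(tps))
  if (!is.null(espec)) {
    for (nm in names(espec$affected)) {
      k <- as.integer(nm)
      if (k < 1 || k > n_blocks) stop("effect guild index out of range: ", nm)
      dlt[k, ] <- espec$affected[[nm]]
    }
  }

  sim <- with_stream(design$seed, "abundance", {
    mu <- stats::rnorm(p, 0, 1)
    u <- matrix(stats::rnorm(p * design$n_subjects, 0, gspec$subject_sd),
                nrow = p)                      # feature x subject fingerprint
    s_shift <- stats::rnorm(n_samp, 0, gspec$sample_sd)
    z <- matrix(stats::rnorm(max(membership) * n_samp), ncol = n_samp)
    eps <- matrix(stats::rnorm(p * n_samp), nrow = p)
    si <- match(grid$subject_id, subj)
    ti <- match(grid$timepoint, tps)
    logx <- mu + u[, si, drop = FALSE] +
      sqrt(rho) * gspec$feature_sd * z[membership, , drop = FALSE] +
      sqrt(1 - rho) * gspec$feature_sd * eps +
      dlt[membership, ti, drop = FALSE] +
      matrix(s_shift, nrow = p, ncol = n_samp, byrow = TRUE)
    x <- exp(logx)
    rel <- sweep(x, 2L, colSums(x), "/")
    if (mode == "counts") matrix(stats::rpois(length(rel), rel * depth),
                                 nrow = p) else rel
  })
  dimnames(sim) <- list(feature_ids, grid$sample_id)
  tab <- abundance_table(sim, mode = mode)

  md <- as_sample_metadata(data.frame(
    sample_id = grid$sample_id, subject_id = grid$subject_id,
    timepoint = grid$timepoint,
    sex = rep(c("F", "M"), c(design$n_female,
                             design$n_subjects - design$n_female))[
      match(grid$subject_id, subj)],
    stringsAsFactors = FALSE))

  truth <- list(membership = membership,
                effects = dlt,
                timepoints = tps,
                n_planted_blocks = n_blocks)
  list(table = tab, metadata = md, truth = truth)
}

#' Simulate metabolite concentrations coupled to one guild
#'
#' `conc = intercept + slope * AST(target-guild relative abundance) +
#'  subject intercept + noise`, truncated at 0.
#'
#' @param table relative-mode [abundance_table] from [simulate_abundance].
#' @param metadata matching metadata.
#' @param truth the `truth` component from [simulate_abundance].
#' @param mspec a [metabolite_spec].
#' @param seed integer seed (its own stream).
#' @return analytes x samples concentration matrix.
#' @export
simulate_metabolites <- function(table, metadata, truth, mspec, seed = 1) {
  if (!inherits(mspec, "metabolite_spec")) stop("`mspec` must be a metabolite_spec")
  k <- mspec$target_guild
  if (!k %in% truth$membership)
    stop("unknown target guild index: ", k)
  members <- names(truth$membership)[truth$membership == k]
  g_ab <- colSums(table[members, , drop = FALSE])
  ast <- ast_transform(pmin(pmax(g_ab, 0), 1))
  an <- mspec$analytes
  subj <- unique(metadata$subject_id)
  si <- match(metadata$subject_id, subj)
  conc <- with_stream(seed, "metabolites", {
    out <- matrix(0, nrow = nrow(an), ncol = ncol(table))
    for (a in seq_len(nrow(an))) {
      u <- stats::rnorm(length(subj), 0, an$subject_sd[a])
      e <- stats::rnorm(ncol(table), 0, an$residual_sd[a])
      out[a, ] <- pmax(an$intercept[a] + an$slope[a] * ast + u[si] + e, 0)
    }
    out
  })
  dimnames(conc) <- list(an$name, colnames(table))
  conc
}

#' Simulate a per-subject paired (baseline, follow-up) outcome
#'
#' `followup = baseline + delta + noise`; used to exercise the
#' normality-gated paired-test cascade.
#'
#' @param design a [cohort_design].
#' @param delta true mean change.
#' @param sd standard deviation of the change (>= 0).
#' @param baseline_mean,baseline_sd distribution of the baseline value.
#' @param seed integer seed (its own stream); defaults to the design seed.
#' @return data.frame with columns `subject_id`, `baseline`, `followup`.
#' @export
simulate_paired_outcome <- function(design, delta, sd,
                                    baseline_mean = 100, baseline_sd = 10,
                                    seed = design$seed) {
  if (sd < 0) stop("sd must be >= 0")
  n <- design$n_subjects
  with_stream(seed, "outcomes", {
    b <- stats::rnorm(n, baseline_mean, baseline_sd)
    f <- b + delta + stats::rnorm(n, 0, sd)
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               baseline = b, followup = f, stringsAsFactors = FALSE)
  })
}
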