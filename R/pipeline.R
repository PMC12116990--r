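# End-to-end orchestration: simulate/load -> filter -> guilds -> screen ->
# ordinate -> associate, with config validation, derived per-stage seeds
# and a run manifest.

pipeline_defaults <- function() {
  list(seed = 1L,
       min_prevalence = 0.20,
       alpha = 0.001,
       n_permutations = 9999L,
       q_threshold = 0.25,
       baseline = "0",
       metric = "bray_curtis",
       correlation = "within",
       posthoc = "nemenyi")
}

known_config_keys <- function() {
  c(names(pipeline_defaults()),
    "abundance", "metadata", "metabolites", "out_dir", "simulate")
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config, fills documented defaults and validates every
#' parameter against its range before any stage runs. All problems are
#' reported together, not first-error-only.
#'
#' @param path YAML config file, or a named list.
#' @return the validated config list; on any problem an error whose
#'   `errors` condition field lists every violation.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  if (!is.list(cfg)) stop("config must be a key: value mapping")
  errs <- character()
  unknown <- setdiff(names(cfg), known_config_keys())
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  def <- pipeline_defaults()
  for (k in names(def)) if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]

  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$min_prevalence) && cfg$min_prevalence > 0 &&
        cfg$min_prevalence <= 1, "min_prevalence must be in (0, 1]")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(cfg$n_permutations) && cfg$n_permutations >= 1,
      "n_permutations must be >= 1")
  chk(is.numeric(cfg$q_threshold) && cfg$q_threshold > 0 &&
        cfg$q_threshold <= 1, "q_threshold must be in (0, 1]")
  chk(is.numeric(cfg$seed), "seed must be numeric")
  chk(cfg$metric %in% c("bray_curtis", "jaccard", "euclidean_z"),
      "metric must be one of bray_curtis, jaccard, euclidean_z")
  chk(cfg$correlation %in% c("within", "pearson"),
      "correlation must be 'within' or 'pearson'")
  chk(cfg$posthoc %in% c("nemenyi", "dunnett", "both"),
      "posthoc must be nemenyi, dunnett or both")
  if (is.null(cfg$simulate)) {
    for (k in c("abundance", "metadata"))
      if (is.null(cfg[[k]]))
        errs <- c(errs, paste0("missing required input path: ", k))
      else if (!file.exists(cfg[[k]]))
        errs <- c(errs, paste0(k, " file not found: ", cfg[[k]]))
    if (!is.null(cfg$metabolites) && !file.exists(cfg$metabolites))
      errs <- c(errs, paste0("metabolites file not found: ", cfg$metabolites))
  }
  if (length(errs))
    stop(structure(class = c("config_error", "error", "condition"),
                   list(message = paste0("invalid config:\n  - ",
                                         paste(errs, collapse = "\n  - ")),
                        call = sys.call(-1), errors = errs)))
  cfg
}

#' Run the guild pipeline end-to-end
#'
#' Executes simulate/load -> prevalence filter -> guild inference ->
#' feature & guild screening -> ordination with stratified PERMANOVA ->
#' (optionally) guild-metabolite association, writing every stage's TSV
#' outputs plus a JSON manifest capturing all parameters and derived
#' per-stage seeds, so a run can be reproduced from the manifest alone.
#'
#' @param config path to a YAML config or a config list (see
#'   [validate_config]).
#' @param out_dir output directory (created); overrides `out_dir` in the
#'   config.
#' @return invisibly, a list with the main in-memory results
#'   (`partition`, `guild_table`, `screen`, `ordination`, `permanova`,
#'   `association`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = stream_seed(cfg$seed, "simulate"),
                guilds = stream_seed(cfg$seed, "guilds"),
                screen = stream_seed(cfg$seed, "screen"),
                ordinate = stream_seed(cfg$seed, "ordinate"),
                associate = stream_seed(cfg$seed, "associate"))

  if (!is.null(cfg$simulate)) {
    sm <- cfg$simulate
    n_sub <- sm$n_subjects %||% 27
    des <- cohort_design(n_subjects = n_sub,
                         timepoints = sm$timepoints %||% c(-5, 0, 2, 4, 10),
                         n_female = sm$n_female %||% round(n_sub * 16 / 27),
                         seed = seeds$simulate)
    gs <- guild_spec(n_features = sm$n_features %||% 120,
                     block_sizes = sm$block_sizes %||% rep(8L, 10L),
                     within_guild_corr = sm$within_guild_corr %||% 0.7,
                     subject_sd = sm$subject_sd %||% 1,
                     sample_sd = sm$sample_sd %||% 0.3,
                     feature_sd = sm$feature_sd %||% 1)
    es <- if (!is.null(sm$effects))
      effect_spec(sm$effects, timepoints = des$timepoints,
                  baseline = cfg$baseline) else NULL
    sim <- simulate_abundance(des, gs, es)
    tab <- sim$table; md <- sim$metadata
    met <- if (!is.null(sm$metabolites)) {
      an <- do.call(rbind, lapply(sm$metabolites, as.data.frame))
      simulate_metabolites(tab, md, sim$truth,
                           metabolite_spec(an,
                                           sm$target_guild %||% 1L),
                           seed = seeds$simulate)
    }
    write_abundance_table(tab, file.path(out_dir, "abundance.tsv"))
    write_sample_metadata(md, file.path(out_dir, "metadata.tsv"))
    truth_df <- data.frame(feature_id = names(sim$truth$membership),
                           guild = unname(sim$truth$membership))
    utils::write.table(truth_df, file.path(out_dir, "truth_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- read_abundance_table(cfg$abundance, mode = "relative")
    md <- read_sample_metadata(cfg$metadata)
    met <- if (!is.null(cfg$metabolites))
      read_metabolite_table(cfg$metabolites)
  }
  al <- align_samples(tab, md)
  tab <- al$table; md <- al$metadata

  flt <- filter_prevalent(tab, cfg$min_prevalence)
  D_feat <- correlation_distance_matrix(flt$table, md,
                                        method = cfg$correlation)
  tree <- ward_tree(D_feat)
  partition <- cut_tree_to_guilds(tree, D_feat, alpha = cfg$alpha,
                                  n_permutations = cfg$n_permutations,
                                  seed = seeds$guilds)
  gt <- guild_abundance(flt$table, partition)
  utils::write.table(
    data.frame(feature_id = names(partition), guild_id = unname(partition)),
    file.path(out_dir, "guild_partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_abundance_table(gt, file.path(out_dir, "guild_abundance.tsv"),
                        id_column = "guild_id")

  scr <- screen_features(gt, md, baseline = cfg$baseline,
                         q_threshold = cfg$q_threshold,
                         posthoc = cfg$posthoc, seed = seeds$screen)
  utils::write.table(scr, file.path(out_dir, "screen_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  Ds <- sample_distance(gt, metric = cfg$metric)
  ord <- adjusted_pcoa(Ds, md)
  utils::write.table(
    data.frame(sample_id = rownames(ord$coordinates),
               ord$coordinates[, seq_len(min(5, ncol(ord$coordinates))),
                               drop = FALSE]),
    file.path(out_dir, "apcoa_coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  perm <- pairwise_stratified_permanova(Ds, md, baseline = cfg$baseline,
                                        n_permutations = cfg$n_permutations,
                                        seed = seeds$ordinate)
  utils::write.table(perm, file.path(out_dir, "permanova_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  assoc <- NULL
  if (!is.null(met)) {
    assoc <- associate(gt, met, md)
    utils::write.table(assoc, file.path(out_dir, "association_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("microguild")),
                   config = cfg[setdiff(names(cfg), "simulate")],
                   simulate = cfg$simulate,
                   derived_seeds = seeds,
                   filter_report = flt$report,
                   n_guilds = max(partition),
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(partition = partition, guild_table = gt, screen = scr,
                 ordination = ord, permanova = perm, association = assoc,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
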