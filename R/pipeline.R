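#' Pipeline run configuration
#'
#' Bundles everything a reproducible end-to-end run needs: the cohort
#' simulation config, the list of nested models to evaluate, bootstrap
#' settings, and a single global seed that is fanned out deterministically
#' to per-stage child seeds. A YAML file with the same field names can be
#' passed to [run_pipeline()] instead.
#'
#' @param seed Global RNG seed (required).
#' @param sim A [cohort_sim_config()].
#' @param models Character vector of canonical model names (see
#'   [canonical_model_terms()]); non-empty.
#' @param ridge_lambda L2 penalty used in all fits; the small default
#'   stabilizes inner leave-pair-out refits in the ~10-event regime.
#' @param n_bootstrap,alpha BCa bootstrap settings.
#' @param pd_features Features for 1D partial dependence (plus a 2D
#'   MD x GRADX grid when both are modelled).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = cohort_sim_config(),
                            models = c("md", "md_gradx", "md_gradx_pgm"),
                            ridge_lambda = 0.05,
                            n_bootstrap = 200,
                            alpha = 0.05,
                            pd_features = c("md", "gradx", "pgm")) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("`seed` must be set for a reproducible run")
  if (length(models) == 0L) stop("`models` must be non-empty")
  models <- vapply(models, function(m)
    match.arg(m, c("md", "md_gradx", "md_gradx_pgm")), character(1))
  stopifnot(inherits(sim, "cohort_sim_config"))
  structure(list(seed = as.integer(seed), sim = sim,
                 models = unname(models), ridge_lambda = ridge_lambda,
                 n_bootstrap = n_bootstrap, alpha = alpha,
                 pd_features = pd_features),
            class = "pipeline_config")
}

# deterministic child-seed derivation: one global knob, distinct streams
child_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 9973L) %% 2147483647L
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  sim <- if (is.null(sim_args)) cohort_sim_config()
         else do.call(cohort_sim_config, sim_args)
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(args, list(sim = sim)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort, derives migration records from the serial C2
#' volumes, pools follow-up reports into endpoint labels, joins them to
#' the features, evaluates every requested nested model with LPO-CV AUC
#' and BCa bootstrap CI, computes partial dependence grids and the
#' median-GRADX stratification, and writes everything (CSV/JSON plus a
#' checksum manifest) to `out_dir`. Identical config and seed reproduce
#' identical numeric outputs.
#'
#' @param config A [pipeline_config()] or the path to a YAML file with
#'   its fields.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-model `ntcp_eval` objects, the
#'   stratification, the joined modelling table and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <<- c(paths, p)
    p
  }

  sim <- simulate_cohort(config$sim, seed = child_seed(config$seed, 1L))
  emit_csv(sim$cohort, "cohort.csv")
  emit_csv(sim$reports, "reports.csv")
  emit_csv(sim$volumes, "volumes.csv")

  migration <- migration_records(
    sim$volumes, end_day = config$sim$course_length_days)
  emit_csv(migration, "migration.csv")

  labels <- pool_reports(sim$reports)
  emit_csv(labels, "labels.csv")

  # modelling table: features joined to the pooled endpoint, the same
  # join the clinical workflow would perform
  tab <- merge(sim$cohort[setdiff(names(sim$cohort), "label")],
               labels[c("patient_id", "label")], by = "patient_id")
  tab <- tab[order(tab$patient_id), , drop = FALSE]
  if (length(unique(tab$label)) < 2L)
    stop("pipeline stage 'endpoint': pooled labels have a single class")
  emit_csv(tab, "modelling_table.csv")

  evals <- list()
  for (k in seq_along(config$models)) {
    m <- config$models[k]
    ev <- ntcp_evaluate(tab, model = m,
                        ridge_lambda = config$ridge_lambda,
                        n_bootstrap = config$n_bootstrap,
                        alpha = config$alpha,
                        seed = child_seed(config$seed, 10L + k))
    evals[[m]] <- ev
    emit_json(ev[c("auc", "ci_low", "ci_high", "n_pairs", "n_pos",
                   "n_neg", "n_bootstrap", "direction", "terms",
                   "alpha")],
              paste0("evaluation_", m, ".json"))
  }

  full_model <- config$models[length(config$models)]
  fit <- ntcp_fit(tab, model = full_model,
                  ridge_lambda = config$ridge_lambda)
  mains <- split_terms(fit$terms)$mains
  for (f in intersect(config$pd_features, mains)) {
    pd <- partial_dependence(fit, f)
    emit_csv(data.frame(pd$grid, pd = pd$pd), paste0("pd_", f, ".csv"))
  }
  if (all(c("md", "gradx") %in% mains)) {
    pd2 <- partial_dependence(fit, c("md", "gradx"))
    emit_csv(data.frame(pd2$grid, pd = pd2$pd), "pd_md_gradx.csv")
  }

  strat <- stratify_by_median(tab, feature = "gradx")
  emit_json(list(feature = strat$feature, median = strat$median,
                 low = strat$low[c("n", "n_pos", "auc", "auc_flipped")],
                 high = strat$high[c("n", "n_pos", "auc", "auc_flipped")]),
            "stratification.json")

  manifest <- list(
    seed = config$seed,
    models = config$models,
    n_patients = config$sim$n_patients,
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  emit_json(manifest, "manifest.json")

  invisible(list(evaluations = evals, stratification = strat,
                 modelling_table = tab, migration = migration,
                 manifest = manifest, out_dir = out_dir))
}
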