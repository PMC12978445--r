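#' Pipeline configuration
#'
#' Settings for the end-to-end run: data generation, sensitivity screening,
#' per-environment GA optimization and similarity analysis. Defaults are the
#' scaled-down demo (r = 10, reps = 5, 20 generations, population 10) that
#' completes in seconds; production settings would use reps = 20, 40
#' generations and population 15.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param r Morris trajectories per replicate.
#' @param reps screening replicates.
#' @param Num_P,Num_ind,Thr_mut GA settings (see [ga_config()]).
#' @param n_cultivars synthetic panel size.
#' @param k top-k for the similarity consensus.
#' @param n_days weather series length.
#' @param n_keep,min_rsi target-selection policy (see [select_targets()]).
#' @param sens_env which generated environment drives the screening.
#' @param out_dir output directory for report artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, r = 10, reps = 5, Num_P = 20,
                            Num_ind = 10, Thr_mut = 0.7, n_cultivars = 21,
                            k = 4, n_days = 160, n_keep = 8, min_rsi = 0.05,
                            sens_env = "env2", out_dir = tempfile("riceideo_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a flat key = value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; numeric values are
#' converted. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  keys <- setdiff(names(unclass(config)), "out_dir")
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], as.character, character(1))),
             path)
  invisible(path)
}

#' Run the whole inverse-engineering pipeline
#'
#' Executes the three analytical layers end to end on synthetic data:
#' generate the four regional environments and a cultivar panel; screen the
#' 11 coefficients by replicated Morris sampling and select the optimization
#' targets; run the GA in every environment; rank the panel cultivars against
#' the optimized ideotypes. Writes `rsi.csv`, per-environment GA archives and
#' summaries, `similarity.csv`, `frequency.csv`, `pca_scores.csv` and a
#' `manifest.json` recording versions, seeds and settings. Deterministic for
#' a given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result`: `environments`, `panel`,
#'   `screening`, `targets`, `ga_runs`, `ideotypes`, `similarity`,
#'   `n_virtual_cultivars`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[generate] environments + panel (seed %d)", config$seed)
  envs <- generate_environment_set(seed = config$seed, n_days = config$n_days)
  panel <- generate_panel(config$n_cultivars, seed = config$seed + 100)
  write_panel(panel, file.path(config$out_dir, "panel.csv"))

  say("[sensitivity] %d reps x %d trajectories on %s",
      config$reps, config$r, config$sens_env)
  space11 <- default_parameter_space()
  model <- sensitivity_model(envs[[config$sens_env]])
  screening <- replicate_screening(space11, model, r = config$r,
                                   reps = config$reps,
                                   seed = config$seed + 200)
  write_rsi_csv(screening, file.path(config$out_dir, "rsi.csv"))
  targets <- select_targets(screening, n_keep = config$n_keep,
                            min_rsi = config$min_rsi)
  say("[sensitivity] selected targets: %s", paste(targets, collapse = ", "))

  weights <- apply(screening$mean, 1, max)[targets]
  ga_space <- default_parameter_space(targets)
  base <- rice_coefficients()
  ga_runs <- list()
  ideotypes <- list()
  for (i in seq_along(envs)) {
    lab <- names(envs)[i]
    say("[optimize] %s: %d generations x %d individuals",
        lab, config$Num_P, config$Num_ind)
    cfg <- ga_config(Num_P = config$Num_P, Num_ind = config$Num_ind,
                     Thr_mut = config$Thr_mut, seed = config$seed + 300 + i,
                     space = ga_space, weights = weights)
    run <- run_ga(envs[[i]], cfg, base = base)
    write_ga_run(run,
                 file.path(config$out_dir, paste0("ga_archive_", lab, ".csv")),
                 file.path(config$out_dir, paste0("ga_summary_", lab, ".json")))
    ga_runs[[lab]] <- run
    full <- merge_coefficients(base, run$best)
    ideotypes[[lab]] <- c(list(name = paste0("ID", i), group = "ideotype"),
                          as.list(unclass(full)[ga_coefficients()]))
  }
  ideo_df <- do.call(rbind, lapply(ideotypes, as.data.frame))

  say("[similarity] %d cultivars vs %d ideotypes, k = %d",
      nrow(panel), nrow(ideo_df), config$k)
  report <- similarity_report(panel, ideo_df, k = config$k)
  utils::write.csv(as.data.frame(report$similarity),
                   file.path(config$out_dir, "similarity.csv"))
  utils::write.csv(report$frequency$global,
                   file.path(config$out_dir, "frequency.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$pca$scores),
                   file.path(config$out_dir, "pca_scores.csv"))

  n_virtual <- sum(vapply(ga_runs, `[[`, numeric(1), "n_evaluations"))
  manifest <- list(
    package = "riceideo",
    version = as.character(utils::packageVersion("riceideo")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    settings = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    targets = targets,
    n_virtual_cultivars = n_virtual,
    convergence = lapply(ga_runs, function(r)
      list(best_fitness = r$best_fitness,
           generation = convergence_generation(r))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %d virtual cultivars evaluated in %.1f s", n_virtual,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(environments = envs, panel = panel, screening = screening,
                 targets = targets, ga_runs = ga_runs, ideotypes = ideo_df,
                 similarity = report, n_virtual_cultivars = n_virtual,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", x$n_virtual_cultivars, "virtual cultivars across",
      length(x$ga_runs), "environments\n")
  cat("Targets:", paste(x$targets, collapse = ", "), "\n")
  cat("Artifacts in:", x$out_dir, "\n")
  invisible(x)
}
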