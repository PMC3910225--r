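#' Read a cohort from long-format CSV
#'
#' Expected columns: `subject_id`, `rating`, and either `work_frac` or both
#' `work_abs` and `wmax` (work in kpm/min; `work_frac = work_abs / wmax`).
#' Optional columns: `step`, `age`, `sex`, `diagnosis`.  Rows are grouped by
#' subject and sorted by work fraction.  Malformed rows (rating outside
#' \[0, 10\], duplicated (subject, work) pairs, non-positive work) abort
#' with a report naming the offending lines.
#'
#' @param path CSV file with header.
#' @return An `rpe_cohort`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) stop("missing required column: subject_id", call. = FALSE)
  if (!"rating" %in% names(df)) stop("missing required column: rating", call. = FALSE)
  if (!"work_frac" %in% names(df)) {
    if (!all(c("work_abs", "wmax") %in% names(df))) {
      stop("missing required column: work_frac (or work_abs + wmax)", call. = FALSE)
    }
    df$work_frac <- df$work_abs / df$wmax
  }
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- df$rating < 0 | df$rating > 10 | !is.finite(df$rating)
  if (any(bad)) {
    stop("rating outside [0,10] on line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(df$work_frac) | df$work_frac <= 0 | df$work_frac > 1 + 1e-8
  if (any(bad)) {
    stop("work_frac outside (0,1] on line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("subject_id", "work_frac")])
  if (any(dup)) {
    stop("duplicate (subject, work) pair on line(s): ",
         paste(line_no[dup], collapse = ", "), call. = FALSE)
  }
  trajectories <- lapply(split(df, df$subject_id), function(g) {
    g <- g[order(g$work_frac), , drop = FALSE]
    cov <- NULL
    if (any(c("age", "sex", "diagnosis") %in% names(g))) {
      cov <- list()
      if ("age" %in% names(g) && !is.na(g$age[1])) cov$age <- g$age[1]
      if ("sex" %in% names(g) && !is.na(g$sex[1])) cov$sex <- g$sex[1]
      if ("diagnosis" %in% names(g) && !is.na(g$diagnosis[1])) cov$diagnosis <- g$diagnosis[1]
      if (!length(cov)) cov <- NULL
    }
    subject_trajectory(g$subject_id[1], g$work_frac, g$rating, covariates = cov)
  })
  rpe_cohort(unname(trajectories))
}

#' Write a cohort to long-format CSV
#'
#' @param cohort An `rpe_cohort`.
#' @param path Output CSV path.
#' @param truth_path Optional sidecar CSV for ground truth (subject_id,
#'   archetype, family, a, b1, b2, c, d, noise_sd) when the cohort carries it.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  rows <- lapply(cohort$trajectories, function(tr) {
    cv <- tr$covariates
    data.frame(subject_id = tr$subject_id, step = seq_along(tr$x),
               work_frac = tr$x, rating = tr$y,
               age = cv$age %||% NA, sex = cv$sex %||% NA,
               diagnosis = cv$diagnosis %||% NA, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(cohort$truth)) {
    trows <- lapply(cohort$truth, function(t) {
      p <- t$params %||% list()
      data.frame(subject_id = t$subject_id, archetype = t$archetype %||% NA,
                 family = t$family %||% NA,
                 a = p$a %||% NA, b1 = p$b1 %||% NA, b2 = p$b2 %||% NA,
                 c = p$c %||% NA, d = p$d %||% NA,
                 noise_sd = t$noise_sd %||% NA, stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, trows), truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Exactly one of `input_csv` (a cohort on disk) or `generator` (a
#' [cohort_config()]) must be given.
#'
#' @param input_csv Path to a long-format cohort CSV, or NULL.
#' @param generator A [cohort_config()], or NULL.
#' @param output_dir Directory for all result files (created if needed).
#' @param min_points Minimum observations per retained subject, default 6.
#' @param fit FitConfig for the individual fits.
#' @param mcmc An [mcmc_config()] or NULL to skip the mixed-effects stage.
#' @param mixed_variants Variants to fit when `mcmc` is given.
#' @param clustering List with `K` (or "auto"), `ridge`, `seed`.
#' @param seed Pipeline seed (used where a stage has no explicit seed).
#' @param verbose Print per-stage progress.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_csv = NULL, generator = NULL,
                            output_dir = tempfile("exertraj_run_"),
                            min_points = 6L, fit = fit_config(),
                            mcmc = NULL, mixed_variants = c("MQD", "MQDV"),
                            clustering = list(K = "auto", ridge = 1e-4, seed = 1L),
                            seed = 1L, verbose = TRUE) {
  if (is.null(input_csv) == is.null(generator)) {
    stop("exactly one of input_csv or generator must be supplied", call. = FALSE)
  }
  structure(list(input_csv = input_csv, generator = generator,
                 output_dir = output_dir, min_points = as.integer(min_points),
                 fit = fit, mcmc = mcmc, mixed_variants = mixed_variants,
                 clustering = clustering, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' JSON mirror of [pipeline_config()]; nested objects `generator`, `fit`,
#' `mcmc`, `clustering` map onto the corresponding constructor arguments
#' ([cohort_config()] archetypes are referenced by `archetypes: "default"`).
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- NULL
  if (!is.null(j$generator)) {
    g <- j$generator
    gen <- cohort_config(
      n_subjects = g$n_subjects %||% 100L,
      points_range = g$points_range %||% c(6L, 12L),
      noise_sd = g$noise_sd %||% 0.3,
      round_to_borg = g$round_to_borg %||% FALSE,
      truncate = g$truncate %||% TRUE,
      seed = g$seed %||% (j$seed %||% 1L))
  }
  mcmc <- NULL
  if (!is.null(j$mcmc)) {
    m <- j$mcmc
    mcmc <- mcmc_config(
      n_chains = m$n_chains %||% 3L,
      n_iterations = m$n_iterations %||% 10000L,
      n_post = m$n_post %||% 1000L, thin = m$thin %||% 10L,
      seed = m$seed %||% (j$seed %||% 1L))
  }
  cl <- j$clustering %||% list()
  pipeline_config(
    input_csv = j$input_csv, generator = gen,
    output_dir = j$output_dir %||% tempfile("exertraj_run_"),
    min_points = j$min_points %||% 6L,
    mcmc = mcmc,
    mixed_variants = j$mixed_variants %||% c("MQD", "MQDV"),
    clustering = list(K = cl$K %||% "auto", ridge = cl$ridge %||% 1e-4,
                      seed = cl$seed %||% (j$seed %||% 1L)),
    seed = j$seed %||% 1L, verbose = j$verbose %||% TRUE)
}

stage_msg <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the cohort, apply the minimum-points filter, fit
#' all four families per subject, write parameter/criteria summaries and the
#' RMSE-difference analysis, optionally fit mixed-effects variants, cluster
#' the trajectories, and write a manifest (package version, seeds, config
#' hash, per-stage status).  Every stage's output is persisted under
#' `config$output_dir` before the next starts; a stage failure stops the run
#' with the failing stage named, keeping earlier outputs on disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results (`cohort`, `fits`,
#'   `summary`, `rmse_diff`, `mixed`, `clusters`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(package = "exertraj",
                   version = as.character(utils::packageVersion("exertraj")),
                   seed = config$seed, stages = list())
  results <- list()
  run_stage <- function(name, fun) {
    stage_msg(config, "[%s] ...", name)
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    res
  }

  results$cohort <- run_stage("load", function() {
    if (!is.null(config$input_csv)) read_cohort_csv(config$input_csv)
    else generate_cohort(config$generator)
  })
  results$cohort <- run_stage("filter", function() {
    f <- filter_min_points(results$cohort, config$min_points)
    utils::write.csv(f$report, out("excluded.csv"), row.names = FALSE)
    if (is.null(f$cohort)) stop("no subjects left after filtering")
    write_cohort_csv(f$cohort, out("cohort.csv"),
                     truth_path = if (!is.null(f$cohort$truth)) out("truth.csv"))
    f$cohort
  })
  results$fits <- run_stage("individual_fits", function() {
    cf <- fit_cohort(results$cohort, config = config$fit)
    utils::write.csv(cf$table, out("fits.csv"), row.names = FALSE)
    jsonlite::write_json(cf$table, out("fits.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    cf
  })
  results$summary <- run_stage("summaries", function() {
    s <- summarize_fits(results$fits, results$cohort)
    utils::write.csv(s, out("summary.csv"), row.names = FALSE)
    s
  })
  results$rmse_diff <- run_stage("rmse_differences", function() {
    rd <- rmse_difference_analysis(results$fits, results$cohort)
    utils::write.csv(rd$points, out("rmse_diff.csv"), row.names = FALSE)
    rd
  })
  if (!is.null(config$mcmc)) {
    results$mixed <- run_stage("mixed_effects", function() {
      fits <- lapply(config$mixed_variants, function(v) {
        fit <- fit_mixed(results$cohort, v, config$mcmc)
        write_draws_csv(fit, out(sprintf("draws_%s.csv", v)))
        jsonlite::write_json(
          list(variant = v, psrf = as.list(fit$psrf), max_psrf = fit$max_psrf,
               converged = fit$converged, dic = fit$dic, pD = fit$pD),
          out(sprintf("diagnostics_%s.json", v)), auto_unbox = TRUE, digits = NA)
        utils::write.csv(fit$posterior_summary,
                         out(sprintf("posterior_%s.csv", v)), row.names = FALSE)
        fit
      })
      stats::setNames(fits, config$mixed_variants)
    })
  }
  results$clusters <- run_stage("clustering", function() {
    basis <- trajectory_basis()
    co <- represent_trajectories(results$cohort, basis,
                                 ridge = config$clustering$ridge %||% 1e-4)
    cm <- cluster_trajectories(co, K = config$clustering$K %||% "auto",
                               seed = config$clustering$seed %||% config$seed,
                               basis = basis)
    utils::write.csv(data.frame(subject_id = names(cm$assignment),
                                cluster = unname(cm$assignment)),
                     out("clusters.csv"), row.names = FALSE)
    utils::write.csv(cluster_mean_curves(cm), out("cluster_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(describe_clusters(cm, results$cohort),
                     out("cluster_composition.csv"), row.names = FALSE)
    cm
  })

  # hash covers the analytic configuration, not where it was written
  cfg_echo <- config; cfg_echo$verbose <- NULL; cfg_echo$output_dir <- NULL
  cfg_file <- out("config_echo.json")
  jsonlite::write_json(jsonlite::serializeJSON(cfg_echo), cfg_file,
                       auto_unbox = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  manifest$outputs <- sort(list.files(config$output_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  stage_msg(config, "pipeline complete: %s", config$output_dir)
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (generate a cohort CSV), `fit` (individual fits
#' for a cohort CSV), `run` (full pipeline from a JSON config).  Invoke via
#' `Rscript -e 'exertraj::exertraj_cli()' <subcommand> [args]`.
#' Returns (invisibly) an exit status: 0 on success, 1 on failure — nonzero
#' exactly when a stage fails.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisible integer status.
#' @export
exertraj_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: exertraj <command> [options]",
    "  simulate --out <cohort.csv> [--n <subjects>] [--seed <s>] [--noise-sd <sd>]",
    "  fit      --in <cohort.csv> --out <fits.csv> [--min-points <k>]",
    "  run      --config <config.json>",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  status <- tryCatch({
    if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
    cmd <- args[1]
    switch(cmd,
      simulate = {
        outp <- opt("--out"); if (is.null(outp)) stop("simulate needs --out")
        cfg <- cohort_config(
          n_subjects = as.integer(opt("--n", "100")),
          noise_sd = as.numeric(opt("--noise-sd", "0.3")),
          seed = as.integer(opt("--seed", "1")))
        write_cohort_csv(generate_cohort(cfg), outp,
                         truth_path = opt("--truth-out"))
        message("wrote ", outp)
      },
      fit = {
        inp <- opt("--in"); outp <- opt("--out")
        if (is.null(inp) || is.null(outp)) stop("fit needs --in and --out")
        coh <- read_cohort_csv(inp)
        coh <- filter_min_points(coh, as.integer(opt("--min-points", "6")))$cohort
        if (is.null(coh)) stop("no subjects left after filtering")
        utils::write.csv(fit_cohort(coh)$table, outp, row.names = FALSE)
        message("wrote ", outp)
      },
      run = {
        cfgp <- opt("--config"); if (is.null(cfgp)) stop("run needs --config")
        run_pipeline(read_pipeline_json(cfgp))
      },
      stop("unknown command: ", cmd, "\n", usage))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
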