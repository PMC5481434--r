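#' Pipeline configuration
#'
#' One structured configuration drives all stages. Detector settings are
#' fixed by design (parameter-free contract); the remaining stage
#' parameters default to the analysis constants: presence threshold 1
#' percent, TTP cutoff 24 months, MSS minima 0.80/0.80, k = 10 folds,
#' 5 rounds. Every stochastic stage derives its seed from the global seed
#' plus a stage tag, and the config is echoed verbatim into every output
#' directory.
#'
#' @param outdir output directory.
#' @param seed global seed.
#' @param n_patients,prop_short_ttp,censoring_rate,paired_adjacent_effect
#'   cohort parameters, see [cohort_spec()].
#' @param n_imaged_patients how many patients get rendered tumor/adjacent
#'   core images (image stages are demonstration-scale; marker statistics
#'   use the full cohort table).
#' @param core_diameter_um,pixel_size_um,fov_width_um,fov_height_um scene
#'   geometry, see [scene_spec()].
#' @param presence_threshold core presence call, percent (strict greater).
#' @param ttp_cutoff_months dichotomy cutoff.
#' @param min_sens,min_spec,k,rounds,max_markers,max_candidates MSS
#'   parameters.
#' @param overwrite allow overwriting an existing dataset.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "glycomss_out", seed = 1L,
                            n_patients = 45L, prop_short_ttp = 2 / 3,
                            censoring_rate = 0.15,
                            paired_adjacent_effect = 0.3,
                            n_imaged_patients = 1L,
                            core_diameter_um = 1000, pixel_size_um = 1,
                            fov_width_um = 500, fov_height_um = 400,
                            presence_threshold = 1,
                            ttp_cutoff_months = 24,
                            min_sens = 0.80, min_spec = 0.80,
                            k = 10L, rounds = 5L, max_markers = 3L,
                            max_candidates = 50L, overwrite = FALSE) {
  cfg <- as.list(environment())
  if (cfg$n_patients <= 0) stop("n_patients must be positive")
  structure(cfg, class = "pipeline_config")
}

.cfg_echo <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(dir, "config echoed")
}

log_line <- function(dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", file = file.path(dir, "pipeline.log"), append = TRUE)
  message(msg)
}

#' Run the simulation stage
#'
#' Generates the cohort table and renders tumor and matched adjacent-tissue
#' cores (for the first `n_imaged_patients` patients), writing TIFFs,
#' truth masks, manifest and cohort CSVs to `outdir`.
#'
#' @param config a [pipeline_config()].
#' @return the dataset directory, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$outdir
  .cfg_echo(config, dir)
  cspec <- cohort_spec(n_patients = config$n_patients,
                       prop_short_ttp = config$prop_short_ttp,
                       censoring_rate = config$censoring_rate,
                       paired_adjacent_effect = config$paired_adjacent_effect,
                       seed = stage_seed(config$seed, "cohort"))
  cohort <- generate_cohort(cspec)
  cores <- list()
  n_img <- min(config$n_imaged_patients, nrow(cohort))
  for (i in seq_len(n_img)) {
    pid <- cohort$patient_id[i]
    for (tt in c("tumor", "adjacent")) {
      f <- if (tt == "tumor") 1 else config$paired_adjacent_effect
      sp <- scene_from_markers(
        pct_dual = cohort$dual[i] * f,
        pct_ca199_only = cohort$ca199_only[i] * f,
        pct_stra_only = cohort$stra_only[i] * f,
        core_diameter_um = config$core_diameter_um,
        pixel_size_um = config$pixel_size_um,
        fov_width_um = config$fov_width_um,
        fov_height_um = config$fov_height_um,
        seed = stage_seed(config$seed, paste0("scene-", pid, "-", tt)))
      cores[[length(cores) + 1L]] <-
        list(core_id = paste0(pid, "_", substr(tt, 1, 3)),
             patient_id = pid, tissue_type = tt,
             core = generate_scene(sp))
    }
  }
  write_dataset(cores, cohort, dir, params = unclass(config),
                overwrite = config$overwrite)
  log_line(dir, "simulate: ", nrow(cohort), " patients, ",
           length(cores), " cores rendered")
  invisible(dir)
}

#' Run the quantification stage
#'
#' Reads the tile TIFFs listed in the manifest, computes per-tile tissue
#' and signal maps, derives the five marker percentages, and averages per
#' core with the presence call and category.
#'
#' @param config a [pipeline_config()].
#' @return data.frame (also written to `per_core.csv`): one row per core
#'   with patient, tissue type, the five markers and category.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$outdir
  manifest <- read_manifest(dir)
  missing <- !file.exists(file.path(dir, manifest$file))
  if (any(missing))
    stop("missing tile files: ",
         paste(manifest$file[missing], collapse = ", "))
  rows <- list()
  for (cid in unique(manifest$core_id)) {
    mc <- manifest[manifest$core_id == cid, ]
    tq <- list()
    for (tid in sort(unique(mc$tile_id))) {
      mt <- mc[mc$tile_id == tid, ]
      imgs <- lapply(seq_len(nrow(mt)), function(i)
        read_tiff(file.path(dir, mt$file[i])))
      names(imgs) <- paste0("r", mt$round, "_", mt$channel)
      tissue <- compute_tissue_mask(imgs)
      ca199 <- find_signal(imgs[["r2_glycan"]], tissue)
      stra <- find_signal(imgs[["r3_glycan"]], tissue)
      tq[[length(tq) + 1L]] <- quantify_markers(ca199, stra, tissue)
    }
    cq <- aggregate_core(tq, core_id = cid,
                         presence_threshold = config$presence_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      core_id = cid, patient_id = mc$patient_id[1],
      tissue_type = mc$tissue_type[1],
      as.list(cq$markers), category = cq$category,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  write.csv(out, file.path(dir, "per_core.csv"), row.names = FALSE)
  log_line(dir, "quantify: ", nrow(out), " cores")
  out
}

#' Run the statistics stage
#'
#' Paired tumor-vs-adjacent elevation tests with BH FDR over the five
#' markers, short-vs-long rank-sum tests, and a Kaplan-Meier / log-rank
#' analysis of the median split of each marker, all from the cohort CSV.
#'
#' @param config a [pipeline_config()].
#' @return list with `elevation`, `rank_sum` and `survival` data.frames
#'   (each also written as CSV).
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$outdir
  cohort <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  markers <- c("ca199", "stra", "ca199_only", "stra_only", "dual")

  elevation <- tryCatch(
    paired_elevation_tests(cohort[markers],
                           setNames(cohort[paste0("adj_", markers)],
                                    markers)),
    error = function(e) {
      warning("elevation tests skipped: ", conditionMessage(e))
      NULL
    })

  cls <- dichotomize_ttp(cohort$ttp_months, cohort$event,
                         config$ttp_cutoff_months)
  keep <- cls != "indeterminate"
  rank_sum <- do.call(rbind, lapply(markers, function(mk) {
    tst <- rank_sum_test(cohort[[mk]][keep & cls == "short"],
                         cohort[[mk]][keep & cls == "long"])
    data.frame(marker = mk, statistic = tst$statistic, p = tst$p_value,
               n_short = tst$n_used[1], n_long = tst$n_used[2],
               stringsAsFactors = FALSE)
  }))

  surv <- do.call(rbind, lapply(markers, function(mk) {
    grp <- median_split(cohort[[mk]])
    tst <- logrank_test(cohort$ttp_months, cohort$event, grp)
    data.frame(marker = mk, chisq = tst$statistic, p = tst$p_value,
               n_low = sum(grp == "low"), n_high = sum(grp == "high"),
               flagged = tst$flagged, stringsAsFactors = FALSE)
  }))

  if (!is.null(elevation))
    write.csv(elevation, file.path(dir, "elevation_tests.csv"),
              row.names = FALSE)
  write.csv(rank_sum, file.path(dir, "rank_sum_tests.csv"),
            row.names = FALSE)
  write.csv(surv, file.path(dir, "logrank_tests.csv"), row.names = FALSE)
  log_line(dir, "stats: elevation ",
           if (is.null(elevation)) "skipped" else "done",
           ", rank-sum and log-rank done")
  list(elevation = elevation, rank_sum = rank_sum, survival = surv)
}

#' Run the MSS stage
#'
#' Searches panels over the three derived markers (CA19-9-only, sTRA-only,
#' dual) on the determinate short/long patients, writes the qualifying
#' panels (JSON), a Table-1-style cross-validation report and a
#' random-label null report (CSV, absent splits as empty cells).
#'
#' @param config a [pipeline_config()].
#' @return list with `panels`, `cv` and `null` (the two `cv_report`s).
#' @export
run_mss <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$outdir
  cohort <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  cls <- dichotomize_ttp(cohort$ttp_months, cohort$event,
                         config$ttp_cutoff_months)
  keep <- cls != "indeterminate"
  dat <- cohort[keep, c("ca199_only", "stra_only", "dual")]
  lab <- droplevels(cls[keep])
  if (min(table(lab)) < 2) stop("a class has fewer than 2 members")

  panels <- search_panels(dat, lab, min_sens = config$min_sens,
                          min_spec = config$min_spec,
                          max_markers = config$max_markers,
                          max_candidates = config$max_candidates,
                          case_label = "short")
  top <- if (nrow(panels) > 0) {
    rule <- panel_rule_from_row(panels, 1)
    list(markers = rule$markers, thresholds = rule$thresholds,
         case_states = rule$case_states,
         state_table = compact_state_table(rule),
         training = as.data.frame(panels[1, c("tp", "fn", "fp", "tn",
                                              "sensitivity", "specificity",
                                              "accuracy")]))
  } else NULL
  jsonlite::write_json(
    list(n_panels = attr(panels, "n_panels"), top_panel = top),
    file.path(dir, "panels.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)

  cv <- cross_validate(dat, lab, k = config$k, rounds = config$rounds,
                       min_sens = config$min_sens,
                       min_spec = config$min_spec,
                       max_markers = config$max_markers,
                       max_candidates = config$max_candidates,
                       seed = stage_seed(config$seed, "cv"),
                       case_label = "short")
  null <- random_label_null(dat, k = config$k, rounds = config$rounds,
                            min_sens = config$min_sens,
                            min_spec = config$min_spec,
                            max_markers = config$max_markers,
                            max_candidates = config$max_candidates,
                            seed = stage_seed(config$seed, "null"))
  write_cv_csv <- function(rep, path) {
    m <- rep$accuracy
    df <- as.data.frame(round(m, 1))
    df$median <- round(rep$round_medians, 1)
    df <- cbind(round = rownames(m), df)
    write.csv(df, path, row.names = FALSE, na = "")
  }
  write_cv_csv(cv, file.path(dir, "cv_report.csv"))
  write_cv_csv(null, file.path(dir, "cv_null_report.csv"))
  log_line(dir, "mss: ", attr(panels, "n_panels"), " qualifying panels; ",
           "CV overall ", round(cv$overall, 1), "%")
  list(panels = panels, cv = cv, null = null)
}

#' Run all pipeline stages
#'
#' @param config a [pipeline_config()].
#' @return list with the outputs of the quantify, stats and mss stages.
#' @export
run_all <- function(config) {
  run_simulate(config)
  q <- run_quantify(config)
  s <- run_stats(config)
  m <- run_mss(config)
  list(quantify = q, stats = s, mss = m)
}

.parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--overwrite") { out$overwrite <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("missing value for ", a)
    out[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `quantify`, `stats`, `mss`, `all`. Flags:
#' `--config PATH` (JSON with [pipeline_config()] fields), `--seed INT`,
#' `--outdir PATH`, `--overwrite`. Exits non-zero on error when run
#' non-interactively.
#'
#' @param args character vector (default: command-line arguments).
#' @param exit_on_error quit the R session with status 1 on error (the
#'   script default); set `FALSE` to propagate errors as conditions.
#' @return the stage result, invisibly.
#' @export
glycomss_cli <- function(args = commandArgs(trailingOnly = TRUE),
                         exit_on_error = !interactive()) {
  run <- function() {
    if (length(args) < 1)
      stop("usage: glycomss <simulate|quantify|stats|mss|all> [--config PATH]",
           " [--seed INT] [--outdir PATH] [--overwrite]")
    cmd <- args[1]
    opts <- .parse_cli_args(args[-1])
    cfg_args <- list()
    if (!is.null(opts$config))
      cfg_args <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    if (!is.null(opts$seed)) cfg_args$seed <- as.integer(opts$seed)
    if (!is.null(opts$outdir)) cfg_args$outdir <- opts$outdir
    if (isTRUE(opts$overwrite)) cfg_args$overwrite <- TRUE
    cfg_args <- cfg_args[names(cfg_args) %in%
                           names(formals(pipeline_config))]
    config <- do.call(pipeline_config, cfg_args)
    switch(cmd,
           simulate = run_simulate(config),
           quantify = run_quantify(config),
           stats = run_stats(config),
           mss = run_mss(config),
           all = run_all(config),
           stop("unknown subcommand: ", cmd))
  }
  if (!exit_on_error) return(invisible(run()))
  res <- tryCatch(run(), error = function(e) {
    message("error: ", conditionMessage(e))
    quit(status = 1L, save = "no")
  })
  invisible(res)
}
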