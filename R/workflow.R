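#' Pipeline configuration
#'
#' One configuration object drives the full run: simulate (or ingest) ->
#' extract -> dynamics (3- and 6-day) -> ANOVA screen -> SVM diagnosis.
#'
#' @param experiment an [experiment_config()] for synthetic runs, or `NULL`
#'   when ingesting real scans.
#' @param images_dir,meta_csv directory of real scans and its metadata CSV
#'   (used when `experiment` is `NULL`).
#' @param render render synthetic scans and extract features from them
#'   (`TRUE`), or use the fast analytic-truth feature table (`FALSE`).
#' @param write_images keep the rendered PNGs in the run directory.
#' @param spacings interval spacings (days) to analyse.
#' @param drop_final drop the final period of each spacing.
#' @param alpha ANOVA screening level.
#' @param hue_cut,threshold extraction settings (see [extract_features()]).
#' @param cost,gamma classifier settings (see [train_svm()]).
#' @param growth_characteristics characteristics passed to
#'   [growth_fit_report()].
#' @param seed master seed (mandatory for synthetic runs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(experiment = experiment_config(),
                            images_dir = NULL, meta_csv = NULL,
                            render = TRUE, write_images = FALSE,
                            spacings = c(3, 6), drop_final = TRUE,
                            alpha = 0.05, hue_cut = 75, threshold = "otsu",
                            cost = 1, gamma = NULL,
                            growth_characteristics = c("LA", "LP"),
                            seed = NULL) {
  if (is.null(experiment) && (is.null(images_dir) || is.null(meta_csv))) {
    stop("either an experiment config or images_dir + meta_csv is required")
  }
  if (!is.null(experiment) && is.null(seed)) {
    seed <- experiment$master_seed
  }
  if (!is.null(experiment) && is.null(seed)) stop("seed is mandatory for synthetic runs")
  structure(list(
    experiment = experiment, images_dir = images_dir, meta_csv = meta_csv,
    render = render, write_images = write_images, spacings = spacings,
    drop_final = drop_final, alpha = alpha, hue_cut = hue_cut,
    threshold = threshold, cost = cost, gamma = gamma,
    growth_characteristics = growth_characteristics, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `experiment` block maps onto [experiment_config()] (treatment profiles
#' stay at their defaults unless `effect_scale` is given).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  exp_args <- y$experiment %||% list()
  if (!is.null(exp_args$effect_scale)) {
    exp_args$treatments <- default_treatment_profiles(exp_args$effect_scale)
    exp_args$effect_scale <- NULL
  }
  experiment <- if (isTRUE(y$ingest)) NULL else do.call(experiment_config, exp_args)
  args <- y[setdiff(names(y), c("experiment", "ingest"))]
  args$experiment <- experiment
  do.call(pipeline_config, args)
}

#' Run the full diagnosis pipeline
#'
#' Executes simulate (or ingest) -> extract -> dynamics at each spacing ->
#' growth-model comparison -> ANOVA screen -> diagnosis grid, writing every
#' stage's table under `out_dir` together with a manifest (effective
#' settings, seed, package version, and an MD5 hash of every output file).
#' The run is fully deterministic given the seed. Any dropped or missing
#' observation is recorded with a reason, never silently imputed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report_dir <- file.path(out_dir, "report")
  dir.create(report_dir, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## stage 1+2: observations and features
  if (!is.null(cfg$experiment)) {
    sim_dir <- if (cfg$write_images) out_dir else NULL
    exper <- generate_experiment(cfg$experiment, out_dir = sim_dir,
                                 render = cfg$render)
    note("simulate: %d observations (%d missing)", nrow(exper$truth),
         sum(exper$truth$missing))
    csv_write(exper$truth, file.path(out_dir, "truth.csv"))
    if (cfg$render) {
      fb <- extract_features_batch(exper$images, hue_cut = cfg$hue_cut,
                                   threshold = cfg$threshold)
      features <- fb$features
      if (!is.null(fb$skipped)) {
        note("extract: %d observations skipped", nrow(fb$skipped))
        csv_write(fb$skipped, file.path(out_dir, "skipped.csv"))
      }
    } else {
      features <- exper$features
      note("extract: analytic-truth feature table used (render = FALSE)")
    }
  } else {
    meta <- utils::read.csv(cfg$meta_csv, stringsAsFactors = FALSE)
    fb <- extract_features_batch(cfg$images_dir, meta, hue_cut = cfg$hue_cut,
                                 threshold = cfg$threshold)
    features <- fb$features
    if (!is.null(fb$skipped)) csv_write(fb$skipped, file.path(out_dir, "skipped.csv"))
    note("ingest: %d scans measured", nrow(features))
  }
  if (is.null(features$year)) features$year <- 1L
  csv_write(features, file.path(out_dir, "features.csv"))

  ## stage 3: dynamics + growth fits
  schedule <- sort(unique(features$dat))
  dyn_list <- list()
  for (sp in cfg$spacings) {
    scheme <- build_interval_scheme(schedule, sp, drop_final = cfg$drop_final)
    dyn <- dynamic_features(features, scheme)
    dyn_list[[paste0(sp, "d")]] <- dyn
    csv_write(dyn, file.path(out_dir, sprintf("dyn%d.csv", sp)))
    note("dynamics %dd: %d periods, %d rows, %d missing RGR_LA cells",
         sp, nrow(scheme), nrow(dyn), sum(is.na(dyn$RGR_LA)))
  }
  growth <- do.call(rbind, lapply(cfg$growth_characteristics, function(ch)
    growth_fit_report(features, characteristic = ch, position = "FIL")))
  csv_write(growth, file.path(out_dir, "growth_fits.csv"))

  ## stage 4: ANOVA screen
  screens <- list()
  for (nm in names(dyn_list)) {
    sc <- screen_features(dyn_list[[nm]], alpha = cfg$alpha)
    if (is.null(sc)) {
      note("screen %s: not enough replication for ANOVA, skipped", nm)
      next
    }
    sc$spacing <- nm
    screens[[nm]] <- sc
  }
  anova_long <- if (length(screens)) do.call(rbind, screens) else NULL
  if (!is.null(anova_long)) {
    rownames(anova_long) <- NULL
    csv_write(anova_long, file.path(out_dir, "anova.csv"))
    csv_write(anova_wide_table(anova_long), file.path(out_dir, "anova_wide.csv"))
  }

  ## stage 5: diagnosis grid
  pos_present <- intersect(c("FIL", "1st", "2nd", "3rd"),
                           unique(features$leaf_position))
  combined <- if (all(c("FIL", "3rd") %in% pos_present)) {
    list(c("FIL", "3rd"))
  } else {
    list()
  }
  grid <- evaluate_grid(dyn_list, positions = pos_present,
                        combined_positions = combined,
                        cost = cfg$cost, gamma = cfg$gamma)
  csv_write(grid$report, file.path(out_dir, "report", "diagnosis.csv"))
  csv_write(best_position_summary(grid$report),
            file.path(out_dir, "report", "best_position.csv"))
  jsonlite::write_json(grid$confusions, file.path(out_dir, "report", "confusions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  ## manifest (deterministic: no timestamps)
  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("riceleafdyn")),
    seed = cfg$seed,
    settings = list(spacings = cfg$spacings, alpha = cfg$alpha,
                    hue_cut = cfg$hue_cut, cost = cfg$cost,
                    render = cfg$render, drop_final = cfg$drop_final),
    files = hashes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = out_dir, features = features, dyn = dyn_list,
                 growth = growth, anova = anova_long, grid = grid))
}

#' Render a Markdown summary of a completed run
#'
#' Collects the run directory's tables into one human-readable report:
#' growth-model comparison, the ANOVA grid with significance stars, the
#' diagnosis accuracy table and the best-position summary. Sections whose
#' artifact is absent are marked absent; the report is still produced.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @param file output path (default `report/report.md` inside the run).
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report", "report.md")) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  lines <- c("# Rice leaf nitrogen diagnosis - run summary", "")
  md_table <- function(df, digits = 3) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(as.character(unlist(df[i, ])), collapse = " | "), "|"), ""))
  }
  section <- function(title, path, digits = 3, max_rows = Inf) {
    lines <<- c(lines, paste("##", title), "")
    f <- file.path(run_dir, path)
    if (!file.exists(f)) {
      lines <<- c(lines, paste0("*absent: ", path, "*"), "")
      warning("missing artifact: ", path)
      return(invisible())
    }
    df <- utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) > max_rows) df <- utils::head(df, max_rows)
    lines <<- c(lines, md_table(df, digits), "")
  }
  section("Growth-model comparison (FIL)", "growth_fits.csv", digits = 4)
  section("ANOVA screen (F values, stars: * p<0.05 ** p<0.01 *** p<0.001)",
          "anova_wide.csv")
  section("Diagnosis accuracy (training / LOOCV validation)",
          "report/diagnosis.csv")
  section("Best leaf position per data set", "report/best_position.csv")
  writeLines(lines, file)
  invisible(file)
}
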