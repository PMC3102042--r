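#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file. Recognized keys: `paths` (`peak_table`,
#' `library`, `training`, `models`, `output`), `time_width_c` (seconds, > 0),
#' `anchors` (list of compound names present in the library, at most 8),
#' `anchor_window_sec` (half-width of the anchor search window, default 60 s;
#' it must cover the raw drift, so it is far wider than `time_width_c`),
#' `weighting` (`intensity_exponent`, `mass_exponent`), `alpha`,
#' `df_convention` ("paper" or "classical"), `min_doc`, `rt_tolerance`
#' (seconds), `mz_min`, `mz_max`, `seed`. Missing optional keys get
#' defaults.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  defaults <- list(time_width_c = 2, alpha = 0.05, df_convention = "paper",
                   anchor_window_sec = 60, min_doc = 0, rt_tolerance = 1.5,
                   mz_min = 85L,
                   mz_max = 500L, seed = 1L,
                   weighting = list(intensity_exponent = 0.5,
                                    mass_exponent = 2))
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  if (!is.numeric(cfg$time_width_c) || cfg$time_width_c <= 0) {
    stop("time_width_c must be > 0 seconds", call. = FALSE)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!cfg$df_convention %in% c("paper", "classical")) {
    stop("df_convention must be 'paper' or 'classical'", call. = FALSE)
  }
  if (!is.null(cfg$anchors) && length(cfg$anchors) > 8L) {
    stop("at most 8 pseudo-internal standards are supported", call. = FALSE)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Validate that a configuration's input files exist
#'
#' @param cfg A `pipeline_config`.
#' @return TRUE invisibly; errors name the first missing path.
#' @export
validate_config_paths <- function(cfg) {
  for (key in c("peak_table", "library", "training", "models")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("configured %s file not found: %s", key, p), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# locate each anchor compound among the observed peaks: highest-DOC peak
# within a wide window of the library RT. The window must be generous enough
# to contain the uncorrected drift itself (a few percent of the run length),
# far wider than the identification window c.
locate_anchors <- function(anchor_names, library, table, window_sec, w) {
  lib_names <- vapply(library, function(e) e$name, character(1))
  rt_old <- numeric(length(anchor_names))
  rt_new <- numeric(length(anchor_names))
  for (i in seq_along(anchor_names)) {
    idx <- match(anchor_names[i], lib_names)
    if (is.na(idx)) {
      stop(sprintf("anchor compound '%s' is not in the reference library",
                   anchor_names[i]), call. = FALSE)
    }
    entry <- library[[idx]]
    v <- weight_spectrum(entry$spectrum, w)
    best_doc <- -Inf
    best_rt <- NA_real_
    for (pk in table$peaks) {
      if (abs(pk$rt - entry$rt) > window_sec) next
      u <- weight_spectrum(pk$spectrum, w)
      if (stats::var(u) == 0 || stats::var(v) == 0) next
      doc <- stats::cor(u, v)
      if (doc > best_doc) {
        best_doc <- doc
        best_rt <- pk$rt
      }
    }
    if (!is.finite(best_doc)) {
      stop(sprintf("anchor compound '%s' (library RT %.1f s) was not matched by any observed peak",
                   anchor_names[i], entry$rt), call. = FALSE)
    }
    rt_old[i] <- entry$rt
    rt_new[i] <- best_rt
  }
  anchor_set(anchor_names, rt_old, rt_new)
}

#' Run the full annotation pipeline
#'
#' Stages, in order: read the aligned-signal table and reconstruct peaks;
#' locate the pseudo-internal standards among the peaks; build the RT map
#' and update the library; identify every peak by windowed weighted-Pearson
#' matching; classify each unidentified peak with the SIMCA models; write
#' the organized matrix. Every peak ends up exactly once as identified,
#' annotated, or unknown. The run is a pure function of its inputs and the
#' seed.
#'
#' @param cfg A `pipeline_config` (or path/list accepted by
#'   [read_pipeline_config()]).
#' @param peak_table_override,library_override,models_override Optional
#'   in-memory inputs replacing the configured file paths (used by tests and
#'   the simulation tools).
#' @return List with `reports` (data.frame: peak_id, rt_sec, status, label,
#'   score), `table` (the `peak_table`), `rt_map`, `identifications`, and
#'   `log` (named counts per category and per class).
#' @export
run_pipeline <- function(cfg, peak_table_override = NULL,
                         library_override = NULL, models_override = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- read_pipeline_config(cfg)
  w <- spectrum_weighting(cfg$weighting$intensity_exponent,
                          cfg$weighting$mass_exponent)
  stage <- "read peak table"
  table <- tryCatch({
    if (!is.null(peak_table_override)) peak_table_override
    else {
      rows <- read_peak_csv(cfg$paths$peak_table)
      group_signals_into_peaks(rows, rt_tolerance = cfg$rt_tolerance,
                               mz_min = cfg$mz_min, mz_max = cfg$mz_max)
    }
  }, error = function(e) stop(sprintf("stage '%s': %s", stage,
                                      conditionMessage(e)), call. = FALSE))
  stage <- "read library"
  library <- tryCatch({
    if (!is.null(library_override)) library_override
    else read_reference_library(cfg$paths$library, cfg$mz_min, cfg$mz_max)
  }, error = function(e) stop(sprintf("stage '%s': %s", stage,
                                      conditionMessage(e)), call. = FALSE))
  rt_map <- NULL
  if (!is.null(cfg$anchors) && length(cfg$anchors) > 0L) {
    anchors <- locate_anchors(unlist(cfg$anchors), library, table,
                              cfg$anchor_window_sec, w)
    rt_map <- build_rt_map(anchors)
    library <- update_library(library, rt_map)
  }
  ids <- identify_all(table, library, c_sec = cfg$time_width_c, w = w,
                      min_doc = cfg$min_doc)
  models <- models_override
  if (is.null(models)) {
    if (!is.null(cfg$paths$models)) {
      models <- read_class_models(cfg$paths$models)
    } else if (!is.null(cfg$paths$training)) {
      training <- read_training_sets(cfg$paths$training, cfg$mz_min,
                                     cfg$mz_max)
      models <- lapply(training, fit_class_model, r = "auto")
    }
  }
  n <- length(table$peaks)
  status <- character(n)
  label <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    if (ids$status[i] == "identified") {
      status[i] <- "identified"
      label[i] <- ids$match_name[i]
      score[i] <- ids$doc[i]
    } else if (!is.null(models)) {
      res <- classify_spectrum(table$peaks[[i]]$spectrum$intensities, models,
                               alpha = cfg$alpha,
                               df_convention = cfg$df_convention)
      if (res$final_label == "unknown") {
        status[i] <- "unknown"
        label[i] <- "unknown"
        score[i] <- 0
      } else {
        status[i] <- "annotated"
        label[i] <- res$final_label
        score[i] <- max(res$per_class$p_value[res$per_class$member])
      }
    } else {
      status[i] <- "unknown"
      label[i] <- "unknown"
      score[i] <- 0
    }
  }
  reports <- data.frame(
    peak_id = vapply(table$peaks, function(p) p$peak_id, character(1)),
    rt_sec = vapply(table$peaks, function(p) p$rt, numeric(1)),
    status = status, label = label, score = score,
    stringsAsFactors = FALSE)
  if (!is.null(cfg$paths$output)) {
    write_organized_matrix(reports, table, cfg$paths$output)
  }
  class_counts <- if (any(status == "annotated")) {
    table(label[status == "annotated"])
  } else table(character(0))
  log <- list(n_peaks = n,
              n_identified = sum(status == "identified"),
              n_annotated = sum(status == "annotated"),
              n_unknown = sum(status == "unknown"),
              annotated_per_class = class_counts)
  message(sprintf("pipeline: %d peaks -> %d identified, %d annotated, %d unknown",
                  n, log$n_identified, log$n_annotated, log$n_unknown))
  list(reports = reports, table = table, rt_map = rt_map,
       identifications = ids, log = log)
}

cli_usage <- function() {
  paste(
    "usage: simca-gc <subcommand> [options]",
    "",
    "subcommands:",
    "  run       --config <file>            run the full pipeline",
    "  fit       --training <csv> --out <json>   fit and serialize SIMCA models",
    "  classify  --models <json> --spectra <csv> --out <csv>",
    "  simulate  --out <dir> [--seed <int>] write a synthetic batch",
    "  validate  --config <file>            check config and input files",
    "common options: --seed <int>, --verbose",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") {
      flags$verbose <- TRUE
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop(sprintf("flag %s needs a value", a),
                                  call. = FALSE)
      flags[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop(sprintf("unknown argument '%s'", a), call. = FALSE)
    }
  }
  flags
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper over the package functions; see
#' `cli_usage()` in the sources or run with no arguments for the subcommand
#' list. Installed as the `exec/simca-gc` script.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly: 0 on success, 1 on runtime failure,
#'   2 on usage errors.
#' @export
gcms_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- argv[1]
  known <- c("run", "fit", "classify", "simulate", "validate")
  if (!sub %in% known) {
    message(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage()))
    return(invisible(2L))
  }
  code <- tryCatch({
    flags <- parse_cli_flags(argv[-1])
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else 1L
    if (sub == "validate") {
      if (is.null(flags$config)) stop("validate needs --config", call. = FALSE)
      cfg <- read_pipeline_config(flags$config)
      validate_config_paths(cfg)
      message("config OK")
    } else if (sub == "run") {
      if (is.null(flags$config)) stop("run needs --config", call. = FALSE)
      cfg <- read_pipeline_config(flags$config)
      if (!is.null(flags$seed)) cfg$seed <- seed
      validate_config_paths(cfg)
      run_pipeline(cfg)
    } else if (sub == "fit") {
      if (is.null(flags$training) || is.null(flags$out)) {
        stop("fit needs --training and --out", call. = FALSE)
      }
      training <- read_training_sets(flags$training)
      models <- lapply(training, fit_class_model, r = "auto")
      write_class_models(models, flags$out)
      message(sprintf("wrote %d class models to %s", length(models),
                      flags$out))
    } else if (sub == "classify") {
      if (is.null(flags$models) || is.null(flags$spectra) ||
          is.null(flags$out)) {
        stop("classify needs --models, --spectra and --out", call. = FALSE)
      }
      models <- read_class_models(flags$models)
      training <- read_training_sets(flags$spectra)
      rows <- do.call(rbind, lapply(training, function(tr) {
        do.call(rbind, lapply(seq_len(nrow(tr$X)), function(k) {
          res <- classify_spectrum(tr$X[k, ], models)
          data.frame(name = tr$compound_names[k],
                     predicted = res$final_label,
                     multi_class = res$multi_class,
                     stringsAsFactors = FALSE)
        }))
      }))
      utils::write.csv(rows, flags$out, row.names = FALSE)
      message(sprintf("classified %d spectra -> %s", nrow(rows), flags$out))
    } else if (sub == "simulate") {
      if (is.null(flags$out)) stop("simulate needs --out", call. = FALSE)
      dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
      templates <- make_default_templates(seed)
      batch <- make_synthetic_batch(templates, seed = seed)
      write_reference_library(batch$library,
                              file.path(flags$out, "library.csv"))
      write_peak_csv(batch$signal_rows,
                     file.path(flags$out, "peak_table.csv"))
      write_training_sets(make_training_sets(templates, seed = seed),
                          file.path(flags$out, "training.csv"))
      utils::write.csv(batch$truth, file.path(flags$out, "truth.csv"),
                       row.names = FALSE)
      message(sprintf("wrote synthetic batch to %s", flags$out))
    }
    0L
  }, error = function(e) {
    message(sprintf("error: %s", conditionMessage(e)))
    if (grepl("needs --|unknown argument|flag --", conditionMessage(e))) 2L
    else 1L
  })
  invisible(code)
}
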