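#' Save and load classifier models
#'
#' Backpropagation models are written as portable JSON (weights plus
#' topology, class levels, feature scaling and config). SVM comparator
#' models contain an external-pointer-free but non-portable `e1071` fit and
#' are stored as RDS.
#'
#' @param model a `plp_bpnn` or `plp_svm`.
#' @param path output path (`.json` for BPNN, `.rds` for SVM).
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   model.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "plp_bpnn")) {
    payload <- list(
      type = "bpnn",
      sizes = model$sizes,
      levels = model$levels,
      scale_I = as.list(model$scale_I),
      config = unclass(model$config),
      W = model$net$W,
      b = model$net$b,
      curves = model$curves
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(model, "plp_svm")) {
    saveRDS(model, path)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (tolower(tools::file_ext(path)) == "rds") {
    return(readRDS(path))
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$type, "bpnn")) stop("not a bpnn model file")
  W <- lapply(payload$W, function(w) {
    w <- as.matrix(w)
    dimnames(w) <- NULL
    w
  })
  cfg <- payload$config
  config <- bpnn_config(cfg$n_classes, hidden = cfg$hidden,
                        epochs = cfg$epochs, lr = cfg$lr,
                        momentum = if (is.null(cfg$momentum)) 0.9 else cfg$momentum,
                        batch_size = cfg$batch_size,
                        val_frac = cfg$val_frac, seed = cfg$seed)
  structure(list(net = list(W = W, b = lapply(payload$b, as.numeric)),
                 levels = payload$levels,
                 scale_I = unlist(payload$scale_I),
                 config = config,
                 curves = payload$curves,
                 sizes = payload$sizes),
            class = "plp_bpnn")
}

#' Load and validate a pipeline run configuration
#'
#' Configurations are YAML with blocks `simulator` (classes, pulse counts,
#' duration, snr, sigma_phi, seed), `processing` (cutoff_hz,
#' threshold_sigma, min_width_us, scheme or schemes), `model`
#' (epochs, lr, batch_size) and `evaluation` (train_frac, seeds). All seeds
#' must be explicit: a run is reproducible from the config alone.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  for (block in c("simulator", "processing", "evaluation")) {
    if (is.null(cfg[[block]])) stop("config is missing the '", block, "' block")
  }
  if (is.null(cfg$simulator$seed)) {
    stop("config validation: simulator.seed is required (no hidden randomness)")
  }
  if (is.null(cfg$evaluation$seeds)) {
    stop("config validation: evaluation.seeds is required")
  }
  structure(cfg, class = "run_config")
}

#' Built-in four-class demonstration configuration
#'
#' The bundled configuration for the four-microalgae comparison (DS, CP, CD,
#' PG) across all five dense-sampling schemes, scaled for a desk run.
#'
#' @param seed base seed.
#' @return A `run_config`.
#' @export
fourclass_demo_config <- function(seed = 1L) {
  read_run_config(list(
    name = "fourclass-demo",
    simulator = list(classes = c("DS", "CP", "CD", "PG"),
                     n_pulses_per_class = 60L, duration = 3,
                     snr = 60, sigma_phi = NULL, seed = seed),
    processing = list(cutoff_hz = 6e4, threshold_sigma = 5,
                      min_width_us = 50,
                      schemes = list("ave", 4L, 10L, 100L, "all")),
    model = list(epochs = 100L, lr = 0.5, batch_size = 32L),
    evaluation = list(train_frac = 0.7, seeds = seed + 0:2)
  ))
}

#' Execute the staged pipeline described by a configuration
#'
#' Runs simulate -> process -> train -> evaluate for every configured scheme
#' and seed via [run_scheme_comparison()], writing the per-run metric tables,
#' the comparison summary and a manifest (config, config file hash, stage
#' counts) into `out_dir`. Rerunning the same configuration reproduces the
#' metric tables byte-identically.
#'
#' @param config a `run_config` (see [read_run_config()]) or path to one.
#' @param out_dir output directory (created if needed).
#' @return The `plp_scheme_comparison`, invisibly; side effect: files in
#'   `out_dir` (`comparison_results.csv`, `comparison_summary.csv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- preset_class_library(cfg$simulator$classes)
  proc <- cfg$processing
  model <- if (is.null(cfg$model)) list() else cfg$model
  stage <- function(what, expr) {
    message(sprintf("[pulsepol] stage %s", what))
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed (config '%s'): %s", what,
                   if (is.null(cfg$name)) "unnamed" else cfg$name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  comparison <- stage("simulate+process+train+evaluate", run_scheme_comparison(
    classes,
    schemes = proc$schemes,
    seeds = as.integer(cfg$evaluation$seeds),
    n_pulses_per_class = cfg$simulator$n_pulses_per_class,
    duration = cfg$simulator$duration,
    snr = if (is.null(cfg$simulator$snr)) 60 else cfg$simulator$snr,
    sigma_phi = cfg$simulator$sigma_phi,
    cap_per_class = if (is.null(proc$cap_per_class)) Inf else proc$cap_per_class,
    epochs = if (is.null(model$epochs)) 100L else model$epochs,
    lr = if (is.null(model$lr)) 0.5 else model$lr,
    batch_size = if (is.null(model$batch_size)) 32L else model$batch_size,
    train_frac = cfg$evaluation$train_frac
  ))
  stage("report", {
    utils::write.csv(comparison$results,
                     file.path(out_dir, "comparison_results.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison$summary,
                     file.path(out_dir, "comparison_summary.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(unclass(cfg), cfg_path)
    manifest <- list(
      package_version = as.character(utils::packageVersion("pulsepol")),
      config_md5 = unname(tools::md5sum(cfg_path)),
      seeds = cfg$evaluation$seeds,
      schemes = vapply(proc$schemes, scheme_label, character(1L)),
      n_results = nrow(comparison$results),
      dense_sampling_gain = comparison$gap
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(comparison)
}

#' Generate committed-scale test fixtures
#'
#' Builds small reference inputs in `dir`: a 0.2 s two-class trace
#' (`tiny`), a 3 s four-class trace (`small`), each with its ground-truth
#' sidecar, plus `known_channels.csv` — hand-checkable channel vectors with
#' their exact Stokes inversions under the ideal analyzer matrix.
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir output directory.
#' @param seed simulation seed.
#' @return Named list of the written paths, invisibly.
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir = tempdir(),
                          seed = 42L) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (size == "tiny") {
    classes <- preset_class_library(c("CD", "PS-10"))
    tr <- simulate_mixture(classes, counts = c(4L, 4L), duration = 0.2,
                           seed = seed)
  } else {
    classes <- preset_class_library(c("DS", "CP", "CD", "PG"))
    tr <- simulate_mixture(classes, counts = rep(15L, 4L), duration = 3,
                           seed = seed)
  }
  trace_path <- file.path(dir, sprintf("%s_trace.tsv", size))
  write_trace(tr, trace_path)
  # channel vectors whose Stokes inversions are known exactly
  known <- rbind(
    unpolarized = c(0.5, 0.5, 0.5, 0.5),   # S = [1, 0, 0, 0]
    rcp = c(0.5, 0.5, 0.0, 1.0),           # S = [1, 0, 0, 1]
    lin0 = c(1.0, 0.5, 0.5, 0.5)           # S = [1, 1, 0, 0]
  )
  stokes_known <- t(apply(known, 1L, invert_stokes, A = ideal_psa_matrix()))
  known_path <- file.path(dir, "known_channels.csv")
  utils::write.csv(
    data.frame(state = rownames(known), known, stokes_known,
               check.names = FALSE), known_path, row.names = FALSE)
  invisible(list(trace = trace_path, known = known_path))
}
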