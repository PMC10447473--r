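#' Read an observation time series from CSV
#'
#' CSV dialect: comma-separated, UTF-8, `.` decimal, header mandatory,
#' 1-based trial indices in the file (internal arrays are 0-based where
#' relevant; the boundary is here).
#'
#' @param path file path.
#' @param schema `"ddm"` (columns `trial,rt,choice[,condition]`) or
#'   `"poisson"` (columns `t,count`).
#' @return validated data.frame; errors name the offending rows.
#' @export
read_timeseries <- function(path, schema = c("ddm", "poisson")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("read_timeseries: no file at ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (schema == "ddm") c("trial", "rt", "choice") else c("t", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_timeseries: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_rows <- function(flag, what) {
    if (any(flag, na.rm = TRUE) || anyNA(flag)) {
      rows <- which(flag | is.na(flag))
      stop("read_timeseries: ", what, " in row(s) ",
           paste(utils::head(rows, 10), collapse = ", "), call. = FALSE)
    }
  }
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v))
      bad_rows(is.na(suppressWarnings(as.numeric(v))), paste0(
        "non-numeric '", cn, "'"))
  }
  if (schema == "ddm") {
    bad_rows(df$rt <= 0, "non-positive rt")
    bad_rows(!df$choice %in% c(0, 1), "choice not in {0,1}")
    if ("condition" %in% names(df))
      bad_rows(df$condition < 0 | df$condition != round(df$condition),
               "invalid condition code")
  } else {
    bad_rows(df$count < 0 | df$count != round(df$count), "invalid count")
  }
  df
}

#' Write an observation time series to CSV
#'
#' @param series data.frame as produced by [observe()] /
#'   [simulate_dataset()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

prior_from_config <- function(cfg) {
  fam <- cfg$family
  cfg$family <- NULL
  lower <- cfg$lower; upper <- cfg$upper
  cfg$lower <- NULL; cfg$upper <- NULL
  do.call(prior_spec, c(list(family = fam), cfg,
                        list(lower = lower, upper = upper)))
}

#' Build a model from a structured-text declaration file
#'
#' The YAML schema mirrors the constructors: a `low_level` section
#' (`kind`, optional `n_drifts`, `sim_dt`, `t_max`), a `transition` section
#' (`kind`, optional `p`, `switch_times`), and an optional `priors` section
#' with `theta0` and `eta` maps of distribution descriptors
#' (`{family: ..., <parameters>, lower, upper}`).
#'
#' @param path YAML file path.
#' @return a [superstat_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("read_model_config: no file at ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$low_level$kind) || is.null(cfg$transition$kind))
    stop("read_model_config: low_level.kind and transition.kind required",
         call. = FALSE)
  th_pr <- NULL
  if (!is.null(cfg$priors$theta0))
    th_pr <- lapply(cfg$priors$theta0, prior_from_config)
  low <- low_level_spec(cfg$low_level$kind,
                        n_drifts = cfg$low_level$n_drifts %||% 1L,
                        theta0_priors = th_pr,
                        sim_dt = cfg$low_level$sim_dt %||% 1e-3,
                        t_max = cfg$low_level$t_max %||% 10)
  eta_pr <- NULL
  if (!is.null(cfg$priors$eta))
    eta_pr <- lapply(cfg$priors$eta, prior_from_config)
  tr <- transition_spec(cfg$transition$kind, eta_priors = eta_pr,
                        p = cfg$transition$p %||% 1L,
                        switch_times = cfg$transition$switch_times)
  superstat_model(low, tr)
}

preset_model <- function(preset) {
  switch(preset,
    "coal" = coal_model(),
    "static-ddm-benchmark" = ddm_model("static"),
    "ddm-random-walk" = ddm_model("random_walk"),
    "gp-ddm" = ddm_model("gp", n_drifts = 4L),
    stop("unknown preset '", preset, "'", call. = FALSE))
}

#' Generate fixture data sets on disk for a named experiment preset
#'
#' Presets: `"coal"` (one Poisson + random-walk series, T = 110, echoing
#' the historical UK coal-mining accident counts setting), `"static-ddm-
#' benchmark"` (`count` static-DDM series of length 100),
#' `"simulation-study"` (`count` series per scenario i-iv at T = 400:
#' static, inter-trial variability, Gaussian random walk, regime switching
#' with jumps at t = 100, 200, 300), `"gp-ddm"` (one 4-condition GP-DDM
#' series). Each record is written as `series_*.csv`, `truth_*.csv`
#' (trajectory incl. the t = 0 row), `eta_*.csv`, plus a `manifest.yaml`
#' holding the preset, seed, and per-record seeds — sufficient to reproduce
#' the directory byte-identically.
#'
#' @param preset preset name.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param count series per preset arm.
#' @param T overridden series length (presets have their canonical
#'   defaults).
#' @return (invisibly) the manifest as a list.
#' @export
make_fixtures <- function(preset, seed, out_dir, count = NULL, T = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- switch(preset,
    "coal" = list(list(tag = "coal", model = coal_model(),
                       T = T %||% 110L, count = count %||% 1L)),
    "static-ddm-benchmark" = list(list(tag = "static_ddm",
                                       model = ddm_model("static"),
                                       T = T %||% 100L,
                                       count = count %||% 100L)),
    "simulation-study" = {
      rs <- transition_spec("regime_switch",
                            switch_times = c(100L, 200L, 300L))
      lapply(list(
        list(tag = "scenario_i_static", tr = "static"),
        list(tag = "scenario_ii_itv", tr = "itv"),
        list(tag = "scenario_iii_random_walk", tr = "random_walk"),
        list(tag = "scenario_iv_regime_switch", tr = rs)),
        function(s) list(tag = s$tag, model = ddm_model(s$tr),
                         T = T %||% 400L, count = count %||% 1L))
    },
    "gp-ddm" = list(list(tag = "gp_ddm",
                         model = ddm_model("gp", n_drifts = 4L),
                         T = T %||% 400L, count = count %||% 1L)),
    stop("make_fixtures: unknown preset '", preset, "'", call. = FALSE))
  set.seed(seed)
  manifest <- list(preset = preset, seed = seed, records = list())
  for (sp in specs) {
    for (i in seq_len(sp$count)) {
      rec_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      sim <- simulate_dataset(sp$model, sp$T, seed = rec_seed)
      stem <- sprintf("%s_%03d", sp$tag, i)
      write_timeseries(sim$series, file.path(out_dir,
                                             paste0("series_", stem, ".csv")))
      th <- data.frame(t = 0:sp$T, sim$theta, check.names = FALSE)
      utils::write.csv(th, file.path(out_dir, paste0("truth_", stem, ".csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as.data.frame(t(sim$eta)),
                       file.path(out_dir, paste0("eta_", stem, ".csv")),
                       row.names = FALSE, quote = FALSE)
      manifest$records[[stem]] <- list(seed = rec_seed, T = sp$T,
                                       tag = sp$tag)
    }
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

config_hash <- function(x) {
  f <- tempfile()
  writeLines(paste(deparse(x), collapse = "\n"), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

log_stage <- function(stage, seed, t0, out) {
  message(sprintf("stage=%s seed=%s elapsed=%.1fs out=%s", stage,
                  as.character(seed),
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  out))
}

#' Run a simulate / train / infer / validate experiment end to end
#'
#' A deliberately small orchestration layer: simulates `n_series` records
#' from a preset model, trains the amortized network at the configured
#' budget, filters every series, and writes a recovery report. All stage
#' outputs, a manifest (config hash, seeds, stage status, checkpoint file),
#' and one structured log line per stage land in `out_dir`; on a stage
#' failure the partial outputs are retained and the manifest marks the
#' failing stage.
#'
#' @param config list with fields `preset`, `seed`, `out_dir`, and
#'   optionally `n_series`, `T`, `draws`, `epochs`, `iter_per_epoch`,
#'   `batch_size`, `hidden`, plus `infer_only` (requires `checkpoint`).
#' @return (invisibly) the manifest list.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config), !is.null(config$preset), !is.null(config$seed),
            !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, hash = config_hash(config),
                   status = "running", failed_stage = NULL)
  write_manifest <- function() yaml::write_yaml(
    manifest, file.path(out_dir, "manifest.yaml"))
  stage <- "simulate"
  result <- try({
    t0 <- Sys.time()
    model <- preset_model(config$preset)
    T <- config$T %||% if (config$preset == "coal") 110L else 100L
    n_series <- config$n_series %||% 5L
    set.seed(config$seed)
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_series)
    sims <- lapply(rec_seeds, function(s) simulate_dataset(model, T, seed = s))
    for (i in seq_along(sims))
      write_timeseries(sims[[i]]$series,
                       file.path(out_dir, sprintf("series_%03d.csv", i)))
    manifest$record_seeds <- rec_seeds
    log_stage(stage, config$seed, t0, out_dir)

    stage <- "train"
    t0 <- Sys.time()
    ckpt <- file.path(out_dir, "checkpoint.rds")
    if (isTRUE(config$infer_only)) {
      if (is.null(config$checkpoint) || !file.exists(config$checkpoint))
        stop("run_experiment: infer_only requires an existing checkpoint",
             call. = FALSE)
      net <- nf_load(config$checkpoint)
    } else {
      fit_model <- if (model$transition$kind == "static")
        superstat_model(model$low_level, transition_spec("random_walk"))
      else model
      net <- nf_init(fit_model,
                     nf_config(hidden = config$hidden %||% 64L),
                     t_pilot = T, seed = config$seed)
      tc <- nf_train_config(epochs = config$epochs %||% 5L,
                            iter_per_epoch = config$iter_per_epoch %||% 10L,
                            batch_size = config$batch_size %||% 16L,
                            t_range = c(T, T))
      net <- nf_train(net, tc, seed = config$seed + 1L)
      nf_save(net, ckpt)
    }
    manifest$checkpoint <- ckpt
    log_stage(stage, config$seed, t0, ckpt)

    stage <- "infer"
    t0 <- Sys.time()
    fits <- lapply(sims, function(s)
      amortized_filter(net, s$series, n = config$draws %||% 250L))
    for (i in seq_along(fits)) {
      s <- filter_summary(fits[[i]])
      utils::write.csv(
        data.frame(t = seq_len(fits[[i]]$T), mean = s$mean, sd = s$sd),
        file.path(out_dir, sprintf("posterior_%03d.csv", i)),
        row.names = FALSE)
    }
    log_stage(stage, config$seed, t0, out_dir)

    stage <- "validate"
    t0 <- Sys.time()
    rep <- recovery(sims, fits, t_scatter = min(99L, T))
    utils::write.csv(data.frame(t = seq_len(nrow(rep$mae)), rep$mae),
                     file.path(out_dir, "recovery_mae.csv"),
                     row.names = FALSE)
    if (!is.null(rep$scatter))
      utils::write.csv(rep$scatter, file.path(out_dir, "recovery_scatter.csv"),
                       row.names = FALSE)
    log_stage(stage, config$seed, t0, out_dir)
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- as.character(result)
    write_manifest()
    stop("run_experiment: stage '", stage, "' failed: ",
         as.character(result), call. = FALSE)
  }
  manifest$status <- "ok"
  write_manifest()
  invisible(manifest)
}
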