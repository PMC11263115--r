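#' Load a run configuration
#'
#' Reads a flat YAML file whose keys are the [sim_params()] fields plus the
#' run-control keys `n_replicates`, `record_every`, `assay_every`, and
#' `out`. Unknown keys are rejected; missing keys take the scaled-down
#' defaults. Values are validated with the same range checks as
#' [sim_params()], errors naming the offending key.
#'
#' @param path Path to a YAML config file.
#' @return Object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  # keep bare Y/N/yes/no tokens (notably the population-size key "N") as
  # strings instead of YAML 1.1 booleans
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                               "bool#no" = function(x) x))
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

run_control_keys <- c("n_replicates", "record_every", "assay_every", "out")

as_run_config <- function(raw) {
  param_keys <- setdiff(names(formals(sim_params)), "preset")
  unknown <- setdiff(names(raw), c(param_keys, run_control_keys, "preset"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(sim_params, raw[intersect(names(raw), c(param_keys, "preset"))])
  ctrl <- list(n_replicates = 1L, record_every = 1L, assay_every = 1L,
               out = NULL)
  for (key in intersect(names(raw), run_control_keys)) ctrl[[key]] <- raw[[key]]
  for (key in c("n_replicates", "record_every", "assay_every")) {
    v <- ctrl[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop(sprintf("parameter '%s' must be an integer >= 1", key), call. = FALSE)
    ctrl[[key]] <- as.integer(v)
  }
  structure(c(list(params = params), ctrl), class = "run_config")
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` restores
#' the configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- c(unclass(config$params),
            config[setdiff(run_control_keys, "out")])
  if (!is.null(config$out)) flat$out <- config$out
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %d replicate(s), record every %d, assay every %d\n",
              x$n_replicates, x$record_every, x$assay_every))
  print(x$params)
  invisible(x)
}

#' Run replicate simulations and pool equilibrium summaries
#'
#' Runs `n_replicates` independent simulations, replicate `r` seeded with
#' `seed + r`, summarises each over the trailing window, and pools the
#' per-replicate equilibrium means into a grand mean and standard error
#' (standard error is `NA` with a single replicate). A replicate that goes
#' extinct is recorded (with its extinction generation) and excluded from
#' pooling rather than failing the batch.
#'
#' @param config A `run_config` (or a [sim_params()] object, in which case
#'   the remaining arguments apply).
#' @param n_replicates Number of replicates when `config` is a
#'   `sim_params`.
#' @param record_every,assay_every Metric cadences.
#' @return Object of class `replicate_summary`: `per_replicate` (data frame
#'   of equilibrium means, one row per replicate), `pooled` (data frame
#'   with mean and SE per metric), `extinct` (named integer vector), and a
#'   `provenance` list (base seed, parameters, package version).
#' @export
run_replicates <- function(config, n_replicates = NULL, record_every = 1L,
                           assay_every = 1L) {
  if (inherits(config, "sim_params")) {
    params <- config
    n_rep <- if (is.null(n_replicates)) 1L else as.integer(n_replicates)
  } else {
    stopifnot(inherits(config, "run_config"))
    params <- config$params
    n_rep <- config$n_replicates
    record_every <- config$record_every
    assay_every <- config$assay_every
  }
  base_seed <- params$seed
  rows <- list()
  extinct <- integer(0)
  for (r in seq_len(n_rep)) {
    p_r <- params
    p_r$seed <- as.integer(base_seed + r)
    sim <- withCallingHandlers(
      run_simulation(p_r, record_every = record_every,
                     assay_every = assay_every),
      warning = function(w) {
        if (grepl("extinct", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!is.na(sim$extinct_at)) {
      extinct[as.character(r)] <- sim$extinct_at
      next
    }
    eq <- summarize_equilibrium(sim, max(1L, min(params$window %/% record_every,
                                                 nrow(sim$metrics))))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(replicate = r, seed = p_r$seed), t(eq$means))
  }
  per_rep <- if (length(rows)) do.call(rbind, rows) else NULL
  pooled <- NULL
  if (!is.null(per_rep)) {
    metric_cols <- setdiff(names(per_rep), c("replicate", "seed"))
    m <- vapply(metric_cols, function(cl) mean(per_rep[[cl]], na.rm = TRUE),
                numeric(1))
    se <- vapply(metric_cols, function(cl) {
      v <- per_rep[[cl]][!is.na(per_rep[[cl]])]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
    pooled <- data.frame(metric = metric_cols, mean = m, se = se,
                         row.names = NULL)
  }
  structure(list(per_replicate = per_rep, pooled = pooled, extinct = extinct,
                 provenance = list(seed = base_seed, params = params,
                                   n_replicates = n_rep,
                                   package_version =
                                     as.character(utils::packageVersion("selfID")))),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("replicate_summary: %d replicate(s), base seed %d (selfID %s)\n",
              pr$n_replicates, pr$seed, pr$package_version))
  if (length(x$extinct))
    cat("  extinct replicates:",
        paste(sprintf("%s (gen %d)", names(x$extinct), x$extinct),
              collapse = ", "), "\n")
  if (!is.null(x$pooled)) {
    show <- x$pooled[x$pooled$metric %in%
                       c("alpha_bar", "V_alpha", "mean_mut_copies", "delta0",
                         "corr_alpha_famID", "slope_alpha_wself",
                         "slope_alpha_wout"), ]
    print(show, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' Write a metrics time series as TSV
#'
#' UTF-8 tab-separated values with a header row; undefined entries are
#' written as `NA`. Values round-trip at full double precision through
#' [read_timeseries()].
#'
#' @param records Metrics data frame (or a `selfing_sim`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(records, path) {
  if (inherits(records, "selfing_sim")) records <- records$metrics
  if (is.null(records) || nrow(records) == 0L)
    stop("no records to write", call. = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(records, digits = 17, trim = TRUE,
                            scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a metrics time series written by [write_timeseries()]
#'
#' @param path Path to the TSV file.
#' @return Metrics data frame.
#' @export
read_timeseries <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA")
}
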