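#' Run the individual-based simulation
#'
#' Runs the full life cycle (reproduction with per-offspring selfing
#' decision, meiosis with Poisson crossovers, infinite-sites deleterious and
#' trait mutation, fitness-proportional viability resampling) for
#' `params$generations` generations, recording one metrics row per recorded
#' generation. All randomness derives from `params$seed`, so identical
#' parameters reproduce the trajectory exactly.
#'
#' The default engine is the compiled one; `engine = "r"` runs the same life
#' cycle through the R-level operations ([step_generation()] and friends),
#' which is practical only for small populations and short horizons.
#'
#' @param params A [sim_params()] object.
#' @param engine `"cpp"` (default) or `"r"`.
#' @param record_every Record a metrics row every this many generations.
#' @param assay_every Perform the family assay (the expensive part of a
#'   record) at recorded generations whose index is a multiple of this;
#'   assay-based fields are `NA` elsewhere.
#' @param init Optional starting `population` (defaults to
#'   [initialize_population()]).
#' @return Object of class `selfing_sim`: list with `metrics` (data frame,
#'   one row per recorded generation), `params`, `final_population`, `seed`,
#'   and `extinct_at` (`NA` unless the population went extinct).
#' @examples
#' p <- sim_params(N = 100, generations = 20, window = 10, seed = 42)
#' sim <- run_simulation(p)
#' summary(sim)
#' @export
run_simulation <- function(params, engine = c("cpp", "r"), record_every = 1L,
                           assay_every = 1L, init = NULL) {
  stopifnot(inherits(params, "sim_params"),
            record_every >= 1L, assay_every >= 1L)
  engine <- match.arg(engine)
  set.seed(params$seed)
  pop <- if (is.null(init)) initialize_population(params) else init
  stopifnot(inherits(pop, "population"))

  if (engine == "cpp") {
    res <- .cpp_run_sim(pop, unclass(params), params$generations,
                        as.integer(record_every), as.integer(assay_every))
    extinct_at <- if (res$extinct_at >= 0) res$extinct_at else NA_integer_
    out <- list(metrics = res$metrics, params = params,
                final_population = res$final_population,
                seed = params$seed, engine = engine, extinct_at = extinct_at)
  } else {
    rows <- vector("list", params$generations %/% record_every)
    ri <- 0L
    extinct_at <- NA_integer_
    for (g in seq_len(params$generations)) {
      pop <- tryCatch(step_generation(pop, params),
                      selfID_extinction = function(e) e)
      if (inherits(pop, "selfID_extinction")) {
        extinct_at <- g
        break
      }
      if (g %% record_every == 0L) {
        ri <- ri + 1L
        rows[[ri]] <- metrics_record(pop, params,
                                     assay = if (g %% assay_every == 0L) NULL
                                             else FALSE)
      }
    }
    out <- list(metrics = do.call(rbind, rows[seq_len(ri)]), params = params,
                final_population = if (is.na(extinct_at)) pop else NULL,
                seed = params$seed, engine = engine, extinct_at = extinct_at)
  }
  if (!is.na(out$extinct_at))
    warning(sprintf("population went extinct at generation %d", out$extinct_at),
            call. = FALSE)
  structure(out, class = "selfing_sim")
}

#' @export
print.selfing_sim <- function(x, ...) {
  cat(sprintf("selfing_sim: N = %d, %d generations recorded (seed %d, %s engine)\n",
              x$params$N, nrow(x$metrics), x$seed, x$engine))
  if (!is.na(x$extinct_at))
    cat(sprintf("  population extinct at generation %d\n", x$extinct_at))
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  final: alpha_bar = %.4f, mean deleterious copies = %.2f, delta0 = %s\n",
              last$alpha_bar, last$mean_mut_copies,
              ifelse(is.na(last$delta0), "NA", sprintf("%.4f", last$delta0))))
  invisible(x)
}

#' @export
summary.selfing_sim <- function(object, window = NULL, ...) {
  s <- summarize_equilibrium(object, window)
  s$params <- object$params
  s$extinct_at <- object$extinct_at
  class(s) <- c("summary.selfing_sim", class(s))
  s
}

#' @export
print.summary.selfing_sim <- function(x, ...) {
  cat(sprintf("Equilibrium summary (N = %d, U = %g, s = %g, h = %g, z_c = %g)\n",
              x$params$N, x$params$U, x$params$s, x$params$h, x$params$z_c))
  NextMethod()
}

#' @export
plot.selfing_sim <- function(x, which = c("alpha_bar", "mean_mut_copies",
                                          "delta0", "corr_alpha_famID"), ...) {
  m <- x$metrics
  which <- intersect(which, names(m))
  old <- graphics::par(mfrow = c(length(which), 1),
                       mar = c(3.5, 4, 1, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (cl in which) {
    graphics::plot(m$generation, m[[cl]], type = "l", xlab = "generation",
                   ylab = cl, ...)
  }
  invisible(x)
}
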