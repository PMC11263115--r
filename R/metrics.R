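#' Population-moment variance
#'
#' Variance with denominator `n` (the population moment, not the `n - 1`
#' sample estimator). This is the `V_alpha` used throughout: for a selfing
#' rate bounded in (0, 1) it cannot exceed 0.25, and an even two-point 0/1
#' split attains 0.25 exactly.
#'
#' @param x Numeric vector.
#' @return The population variance.
#' @examples
#' var_pop(c(0, 1, 0, 1)) # 0.25
#' @export
var_pop <- function(x) {
  mean((x - mean(x))^2)
}

cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

pearson_or_na <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  vx <- var_pop(x); vy <- var_pop(y)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cov_pop(x, y) / sqrt(vx * vy)
}

slope_or_na <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  vx <- var_pop(x)
  if (vx <= 0) return(NA_real_)
  cov_pop(x, y) / vx
}

#' Selfed/outcrossed offspring fitness assay
#'
#' For each adult, generates one selfed offspring (two independent meioses
#' from that adult) and one outcrossed offspring (second gamete from a
#' uniformly sampled other adult), recording the deleterious fitness
#' component `w2` only. Assay offspring are never added to the population.
#' Family-level inbreeding depression is `1 - w_self / w_out`, defined only
#' where `w_out > 0`.
#'
#' @param pop A `population`.
#' @param params A [sim_params()] object.
#' @return Data frame with one row per adult: `alpha`, `w_self`, `w_out`,
#'   `family_id` (`NA` where `w_out = 0`).
#' @export
family_assay <- function(pop, params) {
  stopifnot(inherits(pop, "population"))
  if (length(pop$individuals) < 2L)
    stop("need at least 2 adults for the family assay", call. = FALSE)
  tab <- .cpp_family_assay(pop, unclass(params))
  tab$family_id <- ifelse(tab$w_out > 0, 1 - tab$w_self / tab$w_out, NA_real_)
  tab
}

#' Population-level inbreeding depression
#'
#' The ratio-of-means baseline `delta_0 = 1 - mean(w_self) / mean(w_out)`
#' (not the mean of family-level ID values).
#'
#' @param assay A family-assay table with columns `w_self`, `w_out`.
#' @return `delta_0`.
#' @examples
#' population_id(data.frame(w_self = c(0.5, 0.7), w_out = c(0.8, 0.8)))
#' @export
population_id <- function(assay) {
  mwo <- mean(assay$w_out)
  if (mwo <= 0) stop("mean outcrossed-offspring fitness is zero", call. = FALSE)
  1 - mean(assay$w_self) / mwo
}

#' Association statistics between selfing rate and fitness
#'
#' Pearson correlations and least-squares regression slopes of the maternal
#' selfing rate `alpha` against the per-individual deleterious mutation copy
#' count, outcrossed-offspring fitness, selfed-offspring fitness, and
#' family-level inbreeding depression, plus the population summaries
#' (`alpha_bar`, `V_alpha`, mean homozygosity). `rho_self` and `rho_out`
#' feed the analytic inbreeding-depression metrics and default to the
#' regression slopes (set `rho = "pearson"` for the correlation
#' coefficients instead). Families with `w_out = 0` are dropped from the
#' family-ID statistics; the number dropped is reported.
#'
#' @param pop A `population` of at least 3 adults.
#' @param assay Optional family-assay table from [family_assay()]; computed
#'   if missing.
#' @param params A [sim_params()] object (needed only when `assay` is
#'   missing).
#' @param rho Which statistic feeds `rho_self`/`rho_out`: `"slope"`
#'   (default) or `"pearson"`.
#' @param n_bins Number of selfing-rate bins for the attached
#'   homozygosity-by-alpha profile (see [binned_homozygosity()]).
#' @return Object of class `association_summary`.
#' @export
association_summary <- function(pop, assay = NULL, params = NULL,
                                rho = c("slope", "pearson"), n_bins = 10) {
  rho <- match.arg(rho)
  inds <- pop$individuals
  if (length(inds) < 3L) stop("need at least 3 families", call. = FALSE)
  if (is.null(assay)) {
    if (is.null(params)) stop("params required when assay is not supplied",
                              call. = FALSE)
    assay <- family_assay(pop, params)
  }
  alpha <- vapply(inds, `[[`, numeric(1), "alpha")
  nmut <- vapply(inds, function(i) i$n_het + 2 * i$n_hom, numeric(1))
  homo <- vapply(inds, `[[`, numeric(1), "homozygosity")
  a <- assay$alpha
  keep <- assay$w_out > 0
  undefined_alpha <- var_pop(a) <= 0

  pe <- c(nmut = pearson_or_na(alpha, nmut),
          wout = pearson_or_na(a, assay$w_out),
          wself = pearson_or_na(a, assay$w_self),
          family_id = pearson_or_na(a[keep], assay$family_id[keep]))
  sl <- c(nmut = slope_or_na(alpha, nmut),
          wout = slope_or_na(a, assay$w_out),
          wself = slope_or_na(a, assay$w_self),
          family_id = slope_or_na(a[keep], assay$family_id[keep]))

  structure(list(
    pearson = pe, slope = sl,
    rho_self = if (rho == "slope") sl[["wself"]] else pe[["wself"]],
    rho_out = if (rho == "slope") sl[["wout"]] else pe[["wout"]],
    rho_statistic = rho,
    alpha_bar = mean(a), V_alpha = var_pop(a),
    mean_homozygosity = mean(homo),
    homozygosity_profile = binned_homozygosity(pop, n_bins = n_bins),
    n_families = length(a), n_dropped_family_id = sum(!keep),
    undefined = undefined_alpha), class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat("Selfing-rate / fitness association summary\n")
  cat(sprintf("  families: %d (family-ID rows dropped: %d)\n",
              x$n_families, x$n_dropped_family_id))
  cat(sprintf("  alpha_bar = %.4f, V_alpha = %.5f, mean homozygosity = %.4f\n",
              x$alpha_bar, x$V_alpha, x$mean_homozygosity))
  tab <- rbind(pearson = x$pearson, slope = x$slope)
  print(round(tab, 5))
  cat(sprintf("  rho_self = %.5f, rho_out = %.5f (%s)\n",
              x$rho_self, x$rho_out, x$rho_statistic))
  if (x$undefined) cat("  note: zero variance in alpha; correlations undefined\n")
  invisible(x)
}

#' Mean individual homozygosity by selfing-rate bin
#'
#' Bins individuals into `n_bins` equal-width, half-open selfing-rate bins
#' `[lo, hi)` on \[0, 1\] (the last bin closed at 1) and averages the
#' individual homozygosity fraction per bin. Empty bins are reported with
#' `NA` means; bins near 0 and 1 are typically sparse.
#'
#' @param pop A `population`.
#' @param n_bins Number of bins (>= 1).
#' @return Data frame with `bin_lo`, `bin_hi`, `n`, `mean_homozygosity`.
#' @export
binned_homozygosity <- function(pop, n_bins = 10) {
  stopifnot(n_bins >= 1)
  inds <- pop$individuals
  alpha <- vapply(inds, `[[`, numeric(1), "alpha")
  homo <- vapply(inds, `[[`, numeric(1), "homozygosity")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(alpha, edges, rightmost.closed = TRUE), n_bins)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    n = 0L, mean_homozygosity = NA_real_)
  for (b in unique(bin)) {
    out$n[b] <- sum(bin == b)
    out$mean_homozygosity[b] <- mean(homo[bin == b])
  }
  out
}

#' One per-generation metrics record
#'
#' Computes the tracked population summaries for a single generation:
#' mean and variance of the selfing rate, deleterious-load means,
#' homozygosity, baseline inbreeding depression `delta0`, and the
#' association statistics of the family assay. Used by the pure-R engine;
#' the C++ engine computes the identical record internally.
#'
#' @param pop A `population`.
#' @param params A [sim_params()] object.
#' @param assay Optional precomputed [family_assay()] table; set
#'   `assay = FALSE` to skip assay-based fields (recorded as `NA`).
#' @return One-row data frame with the time-series columns.
#' @export
metrics_record <- function(pop, params, assay = NULL) {
  inds <- pop$individuals
  alpha <- vapply(inds, `[[`, numeric(1), "alpha")
  nhet <- vapply(inds, `[[`, numeric(1), "n_het")
  nhom <- vapply(inds, `[[`, numeric(1), "n_hom")
  homo <- vapply(inds, `[[`, numeric(1), "homozygosity")
  rec <- data.frame(
    generation = pop$generation, alpha_bar = mean(alpha),
    V_alpha = var_pop(alpha), mean_mut_copies = mean(nhet + 2 * nhom),
    mean_n_het = mean(nhet), mean_n_hom = mean(nhom),
    mean_homozygosity = mean(homo), delta0 = NA_real_,
    corr_alpha_nmut = pearson_or_na(alpha, nhet + 2 * nhom),
    corr_alpha_wout = NA_real_, corr_alpha_wself = NA_real_,
    corr_alpha_famID = NA_real_, slope_alpha_wself = NA_real_,
    slope_alpha_wout = NA_real_)
  if (!identical(assay, FALSE)) {
    if (is.null(assay)) assay <- family_assay(pop, params)
    keep <- assay$w_out > 0
    rec$delta0 <- if (mean(assay$w_out) > 0)
      1 - mean(assay$w_self) / mean(assay$w_out) else NA_real_
    rec$corr_alpha_wout <- pearson_or_na(assay$alpha, assay$w_out)
    rec$corr_alpha_wself <- pearson_or_na(assay$alpha, assay$w_self)
    rec$corr_alpha_famID <- pearson_or_na(assay$alpha[keep],
                                          assay$family_id[keep])
    rec$slope_alpha_wself <- slope_or_na(assay$alpha, assay$w_self)
    rec$slope_alpha_wout <- slope_or_na(assay$alpha, assay$w_out)
  }
  rec
}

#' Trailing-window equilibrium averages
#'
#' Arithmetic mean of each tracked metric over the last `window` recorded
#' generations, excluding undefined (`NA`) entries; the number of values
#' used per metric is reported alongside.
#'
#' @param records Per-generation metrics: a data frame (as produced by
#'   [run_simulation()]) or a `selfing_sim` object.
#' @param window Number of trailing records to average (defaults to the
#'   run's `window` parameter when `records` is a `selfing_sim`).
#' @return Object of class `equilibrium_summary`: list with `means` (named
#'   numeric), `n_used` (named integer), `window`.
#' @export
summarize_equilibrium <- function(records, window = NULL) {
  if (inherits(records, "selfing_sim")) {
    if (is.null(window)) window <- records$params$window
    records <- records$metrics
  }
  if (is.null(window)) stop("window must be supplied", call. = FALSE)
  n <- nrow(records)
  if (window > n) stop("window exceeds the number of recorded generations",
                       call. = FALSE)
  tail_rec <- records[seq.int(n - window + 1L, n), , drop = FALSE]
  cols <- setdiff(names(tail_rec), "generation")
  means <- vapply(cols, function(cl) mean(tail_rec[[cl]], na.rm = TRUE),
                  numeric(1))
  n_used <- vapply(cols, function(cl) sum(!is.na(tail_rec[[cl]])), integer(1))
  means[n_used == 0L] <- NA_real_
  structure(list(means = means, n_used = n_used, window = window),
            class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf("Equilibrium averages over the trailing %d recorded generations\n",
              x$window))
  tab <- data.frame(mean = signif(x$means, 6), n_used = x$n_used)
  print(tab)
  invisible(x)
}
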