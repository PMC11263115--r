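#' Modifier effect function f(alpha)
#'
#' A rare modifier allele changes the selfing rate of a carrier with
#' background selfing rate `alpha` by `f(alpha)`. Two standard shapes are
#' built in: a constant effect (`f = magnitude`), for which the relative
#' slope `g(alpha_bar) = f'(alpha_bar) / f(alpha_bar)` is 0, and an effect
#' proportional to the outcrossing rate (`f = magnitude * (1 - alpha)`),
#' for which `g(alpha_bar) = -1 / (1 - alpha_bar)`. Custom effects supply
#' `f` (and optionally `fprime`; a central difference is used otherwise).
#'
#' @param kind `"constant"`, `"prop_outcross"`, or `"custom"`.
#' @param magnitude Effect size scaling (constant and proportional kinds).
#' @param f For `kind = "custom"`: a function of `alpha`.
#' @param fprime Optional derivative function for `kind = "custom"`.
#' @return Object of class `modifier_effect` with elements `f` (function)
#'   and `g` (function of `alpha_bar` returning `f'/f`).
#' @examples
#' eff <- modifier_effect("prop_outcross", magnitude = 0.05)
#' eff$f(0.3)
#' eff$g(0.5) # -2
#' @export
modifier_effect <- function(kind = c("constant", "prop_outcross", "custom"),
                            magnitude = 0.01, f = NULL, fprime = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    f_fun <- function(alpha) rep_len(magnitude, length(alpha))
    g_fun <- function(alpha_bar) 0
  } else if (kind == "prop_outcross") {
    f_fun <- function(alpha) magnitude * (1 - alpha)
    g_fun <- function(alpha_bar) -1 / (1 - alpha_bar)
  } else {
    if (!is.function(f)) stop("custom modifier_effect requires f", call. = FALSE)
    f_fun <- f
    g_fun <- if (is.function(fprime)) {
      function(alpha_bar) fprime(alpha_bar) / f_fun(alpha_bar)
    } else {
      function(alpha_bar) {
        eps <- 1e-6
        ((f_fun(alpha_bar + eps) - f_fun(alpha_bar - eps)) / (2 * eps)) /
          f_fun(alpha_bar)
      }
    }
  }
  structure(list(kind = kind, magnitude = magnitude, f = f_fun, g = g_fun),
            class = "modifier_effect")
}

#' Read a per-family table
#'
#' Reads a delimited text file with header columns `alpha`, `w_self`,
#' `w_out` (one row per maternal family), the external interface through
#' which empirical selfed/outcrossed fitness assays can be analysed.
#'
#' @param path Path to a TSV (or other single-character-delimited) file.
#' @param sep Field separator, tab by default.
#' @return Data frame with columns `alpha`, `w_self`, `w_out`.
#' @export
read_family_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("family table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("alpha", "w_self", "w_out")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("family table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab[need]
}

#' Summary inputs for the analytic ID metrics
#'
#' Reduces a per-family table to the quantities entering the analytic
#' inbreeding-depression formulas: mean selfed/outcrossed offspring fitness,
#' the mean and population variance of the selfing rate, and the
#' association statistics `rho_self` and `rho_out`. By default `rho` is the
#' least-squares slope of offspring fitness on maternal selfing rate (the
#' statistic under which the linear approximation is exact); Pearson
#' correlations are available for sensitivity. `w_self_bar` and `w_out_bar`
#' are the least-squares fitted values at `alpha_bar` which, for OLS,
#' coincide exactly with the sample means.
#'
#' @param table Data frame with columns `alpha`, `w_self`, `w_out`.
#' @param rho `"slope"` (default) or `"pearson"`.
#' @return Object of class `theory_inputs`.
#' @export
theory_inputs <- function(table, rho = c("slope", "pearson")) {
  rho <- match.arg(rho)
  stopifnot(all(c("alpha", "w_self", "w_out") %in% names(table)))
  a <- table$alpha
  rs <- if (rho == "slope") slope_or_na(a, table$w_self)
        else pearson_or_na(a, table$w_self)
  ro <- if (rho == "slope") slope_or_na(a, table$w_out)
        else pearson_or_na(a, table$w_out)
  new_theory_inputs(E_wself = mean(table$w_self), E_wout = mean(table$w_out),
                    alpha_bar = mean(a), V_alpha = var_pop(a),
                    rho_self = rs, rho_out = ro, rho_statistic = rho)
}

#' Assemble theory inputs from known summary values
#'
#' Builds a `theory_inputs` object directly from summary statistics (e.g.
#' published means and regression slopes) rather than a per-family table.
#'
#' @param E_wself,E_wout Mean fitness of selfed / outcrossed offspring.
#' @param alpha_bar Mean selfing rate.
#' @param V_alpha Population variance of the selfing rate.
#' @param rho_self,rho_out Association statistics between maternal selfing
#'   rate and selfed / outcrossed offspring fitness.
#' @param w_self_bar,w_out_bar Fitted offspring fitness at `alpha_bar`;
#'   default to the means (exact for least squares).
#' @param rho_statistic Label recording which statistic `rho` is.
#' @return Object of class `theory_inputs`.
#' @export
new_theory_inputs <- function(E_wself, E_wout, alpha_bar, V_alpha,
                              rho_self = 0, rho_out = 0,
                              w_self_bar = E_wself, w_out_bar = E_wout,
                              rho_statistic = "slope") {
  stopifnot(E_wout > 0, V_alpha >= 0, V_alpha <= 0.25)
  structure(list(E_wself = E_wself, E_wout = E_wout,
                 w_self_bar = w_self_bar, w_out_bar = w_out_bar,
                 alpha_bar = alpha_bar, V_alpha = V_alpha,
                 rho_self = rho_self, rho_out = rho_out,
                 rho_statistic = rho_statistic),
            class = "theory_inputs")
}

#' @export
print.theory_inputs <- function(x, ...) {
  cat("Theory inputs\n")
  cat(sprintf("  E[w_self] = %.5f, E[w_out] = %.5f\n", x$E_wself, x$E_wout))
  cat(sprintf("  alpha_bar = %.4f, V_alpha = %.5f\n", x$alpha_bar, x$V_alpha))
  cat(sprintf("  rho_self = %.5f, rho_out = %.5f (%s)\n",
              x$rho_self, x$rho_out, x$rho_statistic))
  invisible(x)
}

#' Invasion fitness of a rare selfing-rate modifier
#'
#' Computes the expected fitness of the resident allele,
#' `w_M = E[alpha w_self(alpha) + (1 - alpha) w_out(alpha)]` (selfed
#' offspring + outcrossed ovules + exported pollen, the pollen term being
#' the population mean of `(1 - alpha) w_out / 2` and identical for both
#' alleles when the modifier is vanishingly rare), and of a rare modifier
#' changing the selfing rate by `f(alpha)`:
#' `w_m = w_M + E[w_self f] - E[w_out f] / 2`. The modifier's advantage is
#' therefore `E[w_self f] - E[w_out f] / 2`, and with
#' `delta_f = 1 - E[w_self f] / E[w_out f]` a selfing-increasing modifier
#' (`E[w_out f] > 0`) invades exactly when `delta_f < 1/2`.
#'
#' @param table Per-family data frame with `alpha`, `w_self`, `w_out`
#'   (expectations are sample means over families).
#' @param effect A [modifier_effect()].
#' @return Object of class `invasion_result` with `w_M`, `w_m`,
#'   `advantage`, `delta_f`, and `invades`.
#' @export
invasion_fitness <- function(table, effect = modifier_effect("constant")) {
  stopifnot(inherits(effect, "modifier_effect"), nrow(table) >= 1)
  a <- table$alpha
  fv <- effect$f(a)
  E_wf_out <- mean(table$w_out * fv)
  if (E_wf_out == 0)
    stop("E[w_out * f(alpha)] is zero; delta is undefined", call. = FALSE)
  E_wf_self <- mean(table$w_self * fv)
  w_M <- mean(a * table$w_self + 0.5 * (1 - a) * table$w_out) +
    0.5 * mean((1 - a) * table$w_out)
  advantage <- E_wf_self - 0.5 * E_wf_out
  structure(list(w_M = w_M, w_m = w_M + advantage, advantage = advantage,
                 delta_f = 1 - E_wf_self / E_wf_out,
                 invades = advantage > 0, effect = effect$kind),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Modifier invasion analysis (f: %s)\n", x$effect))
  cat(sprintf("  w_M = %.6f, w_m = %.6f, advantage = %+.6g\n",
              x$w_M, x$w_m, x$advantage))
  cat(sprintf("  delta_f = %.6f -> modifier %s\n", x$delta_f,
              if (x$invades) "invades (delta_f < 1/2)" else "does not invade"))
  invisible(x)
}

#' Baseline population-level inbreeding depression
#'
#' `delta_0 = 1 - E[w_self] / E[w_out]`, the ratio-of-means ID reported by
#' empirical studies. It is the exact invasion criterion quantity when the
#' modifier effect is constant or when the fitness-selfing associations
#' vanish.
#'
#' @param inputs A `theory_inputs` object.
#' @return `delta_0`.
#' @export
delta_baseline <- function(inputs) {
  1 - inputs$E_wself / inputs$E_wout
}

#' Association-corrected ID for a selfing-rate modifier
#'
#' The linear approximation of the modifier-weighted inbreeding depression:
#' `delta = 1 - (E[w_self] + rho_self V_alpha g) / (E[w_out] + rho_out
#' V_alpha g)` with `g = f'(alpha_bar) / f(alpha_bar)`. With `rho` taken as
#' the regression slope this equals the exact modifier-weighted ID
#' `1 - E[w_self f] / E[w_out f]` whenever `w_self(alpha)`,
#' `w_out(alpha)`, and `f(alpha)` are linear in `alpha`. Reduces to
#' `delta_0` when `g = 0` (constant effect) or when both associations
#' vanish.
#'
#' @param inputs A `theory_inputs` object.
#' @param g Either a [modifier_effect()] (whose `g` is evaluated at
#'   `alpha_bar`) or the numeric relative slope `f'/f` directly.
#' @return The corrected `delta`.
#' @export
delta_modifier <- function(inputs, g = 0) {
  if (inherits(g, "modifier_effect")) g <- g$g(inputs$alpha_bar)
  num <- inputs$E_wself + inputs$rho_self * inputs$V_alpha * g
  den <- inputs$E_wout + inputs$rho_out * inputs$V_alpha * g
  if (abs(den) < .Machine$double.eps^0.5)
    stop("denominator of the corrected delta vanishes", call. = FALSE)
  1 - num / den
}

#' Quantitative-genetic population-level inbreeding depression
#'
#' When the selfing rate is a quantitative trait evolving from standing
#' variation, the ID metric whose comparison with 1/2 gives the direction
#' of evolution of the mean selfing rate:
#' `delta = 1 - (w_self(alpha_bar) + alpha_bar rho_self + (1 - alpha_bar)
#' rho_out / 2) / w_out(alpha_bar)`.
#'
#' @param inputs A `theory_inputs` object.
#' @return The quantitative-genetic `delta`.
#' @export
delta_quantitative <- function(inputs) {
  if (inputs$w_out_bar <= 0)
    stop("w_out(alpha_bar) must be positive", call. = FALSE)
  1 - (inputs$w_self_bar + inputs$alpha_bar * inputs$rho_self +
         0.5 * (1 - inputs$alpha_bar) * inputs$rho_out) / inputs$w_out_bar
}

#' Selection gradient on the mean selfing rate
#'
#' The linear-approximation selection gradient on a quantitative selfing
#' trait: `w_out(alpha_bar) * ((w_self(alpha_bar) + alpha_bar rho_self +
#' (1 - alpha_bar) rho_out / 2) / w_out(alpha_bar) - 1/2)`. Its sign equals
#' the sign of `1/2 - delta_quantitative(inputs)`: the mean selfing rate
#' increases exactly when the quantitative-genetic ID is below one half.
#'
#' @param inputs A `theory_inputs` object.
#' @return The selection gradient.
#' @export
selection_gradient <- function(inputs) {
  if (inputs$w_out_bar <= 0)
    stop("w_out(alpha_bar) must be positive", call. = FALSE)
  num <- inputs$w_self_bar + inputs$alpha_bar * inputs$rho_self +
    0.5 * (1 - inputs$alpha_bar) * inputs$rho_out
  inputs$w_out_bar * (num / inputs$w_out_bar - 0.5)
}

#' Scenario family with a prescribed baseline ID
#'
#' Returns a generator `function(delta)` producing a per-family table whose
#' baseline inbreeding depression equals `delta` exactly: `w_out` fixed,
#' `w_self = (1 - delta) * w_out`, and `alpha` an evenly spaced grid (so
#' fitness is independent of the selfing rate — the association-free case).
#' Used to scan the invasion threshold.
#'
#' @param w_out Outcrossed-offspring fitness (constant across families).
#' @param n Number of families.
#' @param alpha_range Range of the selfing-rate grid.
#' @return Function mapping `delta` to a family table.
#' @export
scenario_fixed_id <- function(w_out = 0.8, n = 200,
                              alpha_range = c(0.05, 0.95)) {
  force(w_out); force(n); force(alpha_range)
  function(delta) {
    data.frame(alpha = seq(alpha_range[1], alpha_range[2], length.out = n),
               w_self = (1 - delta) * w_out, w_out = w_out)
  }
}

#' Invasion / evolution threshold on the ID scale
#'
#' Bisection on the sign of the modifier's invasion advantage (method
#' `"modifier"`) or of the quantitative-trait selection gradient (method
#' `"gradient"`) over a family of scenarios indexed by their inbreeding
#' depression `delta` in `[lower, upper]`. Returns the `delta` at which the
#' sign changes, to within `tol`. For association-free scenarios the
#' threshold is 1/2.
#'
#' @param scenario Function of `delta`: for `"modifier"` it must return a
#'   per-family table (see [scenario_fixed_id()]); for `"gradient"` a
#'   `theory_inputs` object.
#' @param effect A [modifier_effect()] (method `"modifier"` only).
#' @param method `"modifier"` or `"gradient"`.
#' @param lower,upper Scan interval for `delta`.
#' @param tol Bisection tolerance.
#' @return The threshold `delta*`.
#' @examples
#' invasion_threshold(scenario_fixed_id()) # 0.5
#' @export
invasion_threshold <- function(scenario = scenario_fixed_id(),
                               effect = modifier_effect("constant"),
                               method = c("modifier", "gradient"),
                               lower = 0, upper = 1, tol = 1e-6) {
  method <- match.arg(method)
  sign_at <- function(delta) {
    if (method == "modifier") {
      sign(invasion_fitness(scenario(delta), effect)$advantage)
    } else {
      sign(selection_gradient(scenario(delta)))
    }
  }
  s_lo <- sign_at(lower)
  s_hi <- sign_at(upper)
  if (s_lo == 0) return(lower)
  if (s_hi == 0) return(upper)
  if (s_lo == s_hi)
    stop("no sign change of the advantage over the scanned delta interval",
         call. = FALSE)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s_mid <- sign_at(mid)
    if (s_mid == 0) return(mid)
    if (s_mid == s_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Full analytic ID report for a family table
#'
#' Computes the baseline ID, the modifier-weighted ID under one or more
#' effect shapes (both the exact sample version and its linear
#' approximation), the quantitative-genetic ID, the selection gradient, and
#' the constant-effect invasion advantage, from a per-family
#' (alpha, w_self, w_out) table.
#'
#' @param table Per-family data frame (or path readable by
#'   [read_family_table()]).
#' @param effects Named list of [modifier_effect()]s to evaluate.
#' @param rho Association statistic passed to [theory_inputs()].
#' @return Object of class `id_report`.
#' @export
id_report <- function(table,
                      effects = list(constant = modifier_effect("constant"),
                                     prop_outcross = modifier_effect("prop_outcross")),
                      rho = c("slope", "pearson")) {
  if (is.character(table)) table <- read_family_table(table)
  rho <- match.arg(rho)
  inputs <- theory_inputs(table, rho = rho)
  per_effect <- lapply(effects, function(eff) {
    inv <- invasion_fitness(table, eff)
    list(delta_exact = inv$delta_f,
         delta_linear = delta_modifier(inputs, eff),
         advantage = inv$advantage, invades = inv$invades)
  })
  structure(list(inputs = inputs, delta0 = delta_baseline(inputs),
                 effects = per_effect,
                 delta_quantitative = delta_quantitative(inputs),
                 gradient = selection_gradient(inputs),
                 n_families = nrow(table)),
            class = "id_report")
}

#' @export
print.id_report <- function(x, ...) {
  cat(sprintf("Inbreeding-depression report (%d families)\n", x$n_families))
  print(x$inputs)
  cat(sprintf("  delta0 (baseline)        = %.6f\n", x$delta0))
  for (nm in names(x$effects)) {
    e <- x$effects[[nm]]
    cat(sprintf("  delta [f: %-13s] = %.6f (linear approx %.6f), advantage %+.3g -> %s\n",
                nm, e$delta_exact, e$delta_linear, e$advantage,
                if (e$invades) "invades" else "no invasion"))
  }
  cat(sprintf("  delta (quantitative)     = %.6f\n", x$delta_quantitative))
  cat(sprintf("  selection gradient       = %+.6f (%s)\n", x$gradient,
              if (x$gradient > 0) "mean selfing rate increases"
              else if (x$gradient < 0) "mean selfing rate decreases"
              else "at the threshold"))
  invisible(x)
}
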