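#' Simulation parameter set
#'
#' Collects and validates every constant of the individual-based model: a
#' hermaphroditic diploid population of constant size `N` with non-overlapping
#' generations, a polygenic selfing-rate trait under stabilizing viability
#' selection, and recessive-to-partially-recessive deleterious mutations
#' arising under an infinite-sites model on a single chromosome pair.
#'
#' @param N Adult population size (>= 2).
#' @param U Diploid genomic deleterious mutation rate per generation; each
#'   gamete receives Poisson(`U`/2) new mutations at uniform positions.
#' @param s Selection coefficient of deleterious mutations, in \[0, 1\].
#' @param h Dominance coefficient (fraction of `s` expressed in
#'   heterozygotes), in \[0, 1\].
#' @param L Expected number of crossovers per meiosis (Poisson mean).
#' @param n_z Number of additive loci controlling the selfing-rate trait;
#'   locus `j` sits at chromosome position `(j-1)/n_z`.
#' @param U_z Diploid trait mutation rate; each gamete receives
#'   Poisson(`U_z`/2) allele flips at uniformly chosen trait loci.
#' @param k Steepness of the logistic map from trait phenotype `z` to
#'   selfing rate `alpha`.
#' @param z_c Phenotype at which the selfing rate equals 0.5; shifting it
#'   moves the population mean selfing rate.
#' @param lambda Strength of stabilizing viability selection on `z`,
#'   `w1(z) = exp(-lambda * z^2)`.
#' @param generations Number of generations to simulate.
#' @param window Trailing window (in generations) over which equilibrium
#'   metrics are averaged.
#' @param seed Integer seed controlling all randomness of a run.
#' @param preset Optional name of a preset: `"test"` (scaled-down defaults,
#'   `N = 1000`, 1500 generations, window 500) or `"full"` (`N = 20000`,
#'   5000 generations, window 2000, the full study scale). Explicit
#'   arguments override preset values.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(N = 200, generations = 50, window = 20, seed = 1)
#' p$s
#' @export
sim_params <- function(N = 1000, U = 0.5, s = 0.2, h = 0.1, L = 10,
                       n_z = 10, U_z = 0.2, k = 3, z_c = 0, lambda = 0.5,
                       generations = 1500, window = 500, seed = 1L,
                       preset = NULL) {
  p <- list(N = N, U = U, s = s, h = h, L = L, n_z = n_z, U_z = U_z,
            k = k, z_c = z_c, lambda = lambda, generations = generations,
            window = window, seed = seed)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("test", "full"))
    base <- switch(preset,
      test  = list(N = 1000, generations = 1500, window = 500),
      full = list(N = 20000, generations = 5000, window = 2000))
    supplied <- names(as.list(match.call()))[-1]
    for (nm in names(base)) {
      if (!nm %in% supplied) p[[nm]] <- base[[nm]]
    }
  }
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  num1 <- function(key) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("parameter '%s' must be a single non-missing number", key),
           call. = FALSE)
    v
  }
  chk <- function(key, ok, what) {
    if (!ok) stop(sprintf("parameter '%s' %s", key, what), call. = FALSE)
  }
  for (key in c("N", "U", "s", "h", "L", "n_z", "U_z", "k", "z_c", "lambda",
                "generations", "window", "seed")) num1(key)
  chk("N", p$N >= 2 && p$N == round(p$N), "must be an integer >= 2")
  chk("U", p$U >= 0, "must be >= 0")
  chk("s", p$s >= 0 && p$s <= 1, "must lie in [0, 1]")
  chk("h", p$h >= 0 && p$h <= 1, "must lie in [0, 1]")
  chk("L", p$L >= 0, "must be >= 0")
  chk("n_z", p$n_z >= 1 && p$n_z == round(p$n_z), "must be an integer >= 1")
  chk("U_z", p$U_z >= 0, "must be >= 0")
  chk("k", is.finite(p$k) && p$k >= 0, "must be finite and >= 0")
  chk("lambda", p$lambda >= 0, "must be >= 0")
  chk("generations", p$generations >= 1 && p$generations == round(p$generations),
      "must be an integer >= 1")
  chk("window", p$window >= 1 && p$window <= p$generations,
      "must satisfy 0 < window <= generations")
  p$N <- as.integer(p$N)
  p$n_z <- as.integer(p$n_z)
  p$generations <- as.integer(p$generations)
  p$window <- as.integer(p$window)
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sim_params)\n")
  cat(sprintf("  population:   N = %d, generations = %d (window %d), seed = %d\n",
              x$N, x$generations, x$window, x$seed))
  cat(sprintf("  mutations:    U = %g, s = %g, h = %g (infinite sites)\n",
              x$U, x$s, x$h))
  cat(sprintf("  selfing map:  n_z = %d loci, U_z = %g, alpha = logistic(k = %g, z_c = %g)\n",
              x$n_z, x$U_z, x$k, x$z_c))
  cat(sprintf("  selection:    stabilizing lambda = %g, crossovers L = %g\n",
              x$lambda, x$L))
  invisible(x)
}
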