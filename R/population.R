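#' Initialize a founding population
#'
#' Creates `N` individuals free of deleterious mutations, each trait-allele
#' copy drawn independently as A or a with probability 1/2 (so the expected
#' founding phenotype is 0). Equilibrium quantities should only be read
#' after burn-in; see [summarize_equilibrium()].
#'
#' @param params A [sim_params()] object.
#' @return Object of class `population`: a list with `individuals` (length
#'   `N`) and `generation = 0`.
#' @examples
#' pop <- initialize_population(sim_params(N = 10, seed = 1))
#' length(pop$individuals)
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  inds <- lapply(seq_len(params$N), function(i) {
    h1 <- haplotype(sample(c(-1L, 1L), params$n_z, replace = TRUE))
    h2 <- haplotype(sample(c(-1L, 1L), params$n_z, replace = TRUE))
    new_individual(h1, h2, params)
  })
  structure(list(individuals = inds, generation = 0L), class = "population")
}

#' @export
print.population <- function(x, ...) {
  a <- vapply(x$individuals, `[[`, numeric(1), "alpha")
  m <- vapply(x$individuals, function(i) i$n_het + 2 * i$n_hom, numeric(1))
  cat(sprintf("population: %d individuals, generation %d\n",
              length(x$individuals), x$generation))
  cat(sprintf("  mean alpha = %.4f, mean deleterious copies = %.2f\n",
              mean(a), mean(m)))
  invisible(x)
}

#' Produce one gamete by meiosis
#'
#' Draws Poisson(`L`) crossovers at uniform breakpoints, picks the starting
#' chromosome with a fair coin, walks the parental segments, then adds
#' Poisson(`U`/2) new deleterious mutations at uniform positions (trait-locus
#' positions and occupied positions are redrawn) and Poisson(`U_z`/2) trait
#' mutations, each flipping the allele at one uniformly chosen trait locus.
#'
#' @param parent An `individual`.
#' @param params A [sim_params()] object.
#' @return A `haplotype`; the number of crossovers drawn is attached as
#'   attribute `n_crossovers`.
#' @export
make_gamete <- function(parent, params) {
  .cpp_gamete(parent$hap1$traits, parent$hap1$pos,
              parent$hap2$traits, parent$hap2$pos, unclass(params))
}

#' Choose reproduction mode and parents
#'
#' Samples a mother uniformly from the adults, draws a uniform deviate
#' `eps`, and selfs iff `eps < alpha_i` (so the probability of selfing is
#' the mother's selfing rate); otherwise samples a father uniformly among
#' the other adults.
#'
#' @param pop A `population` (or plain list of individuals).
#' @return List with `mother` (index), `mode` (`"self"` or `"outcross"`),
#'   and `father` (index or `NA`).
#' @export
choose_mode_and_parents <- function(pop) {
  inds <- if (inherits(pop, "population")) pop$individuals else pop
  n <- length(inds)
  if (n < 2L) stop("need at least 2 adults to reproduce", call. = FALSE)
  i <- sample.int(n, 1L)
  eps <- stats::runif(1)
  if (eps < inds[[i]]$alpha) {
    list(mother = i, mode = "self", father = NA_integer_)
  } else {
    j <- sample.int(n - 1L, 1L)
    if (j >= i) j <- j + 1L
    list(mother = i, mode = "outcross", father = j)
  }
}

#' Produce one juvenile offspring
#'
#' Combines two gametes: both from the mother (two independent meioses) if
#' the selfing draw succeeds, otherwise one from the mother and one from a
#' uniformly sampled other adult.
#'
#' @inheritParams choose_mode_and_parents
#' @param params A [sim_params()] object.
#' @return An `individual` with all derived fields computed.
#' @export
make_offspring <- function(pop, params) {
  inds <- if (inherits(pop, "population")) pop$individuals else pop
  ch <- choose_mode_and_parents(inds)
  g1 <- make_gamete(inds[[ch$mother]], params)
  g2 <- if (ch$mode == "self") make_gamete(inds[[ch$mother]], params)
        else make_gamete(inds[[ch$father]], params)
  new_individual(g1, g2, params)
}

#' Fitness-proportional viability resampling
#'
#' Samples `N` adults from the juvenile cohort with replacement, with
#' probability proportional to total fitness `w = w1 * w2`. If every
#' juvenile has zero fitness the population is extinct and an error of class
#' `selfID_extinction` is signalled.
#'
#' @param juveniles List of `individual`s.
#' @param N Number of adults to sample.
#' @return List of `N` individuals.
#' @export
viability_selection <- function(juveniles, N) {
  w <- vapply(juveniles, `[[`, numeric(1), "w")
  if (all(w <= 0))
    stop(structure(class = c("selfID_extinction", "error", "condition"),
                   list(message = "population extinct: all juveniles have zero fitness",
                        call = sys.call())))
  idx <- sample.int(length(juveniles), N, replace = TRUE, prob = w)
  juveniles[idx]
}

#' Advance the population by one generation
#'
#' Reproduction (with per-offspring selfing decision, meiosis, and
#' mutation) produces `N` juveniles, followed by fitness-proportional
#' viability resampling back to `N` adults.
#'
#' @param pop A `population`.
#' @param params A [sim_params()] object.
#' @return The next-generation `population`.
#' @export
step_generation <- function(pop, params) {
  stopifnot(inherits(pop, "population"))
  juv <- lapply(seq_len(params$N), function(i) make_offspring(pop, params))
  adults <- tryCatch(viability_selection(juv, params$N),
                     selfID_extinction = function(e) {
                       e$generation <- pop$generation + 1L
                       stop(e)
                     })
  structure(list(individuals = adults, generation = pop$generation + 1L),
            class = "population")
}
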