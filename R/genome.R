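#' Construct a haplotype
#'
#' A haplotype is one chromosome copy: `n_z` trait alleles (stored as -1 for
#' allele A, +1 for allele a; each allele copy shifts the phenotype by
#' -1/n_z or +1/n_z) plus a strictly increasing set of deleterious-mutation
#' positions in (0, 1). Trait loci occupy positions 0, 1/n_z, ...,
#' (n_z - 1)/n_z, which deleterious mutations never hit.
#'
#' @param traits Integer vector of -1/+1 allele states, length `n_z`.
#' @param pos Numeric vector of deleterious-mutation positions, strictly
#'   increasing, unique, in (0, 1), avoiding trait-locus positions.
#' @return Object of class `haplotype`.
#' @examples
#' haplotype(c(-1L, 1L, 1L), pos = c(0.15, 0.72))
#' @export
haplotype <- function(traits, pos = numeric(0)) {
  traits <- as.integer(traits)
  if (length(traits) < 1L || !all(traits %in% c(-1L, 1L)))
    stop("trait alleles must be -1 (A) or +1 (a)", call. = FALSE)
  pos <- as.double(pos)
  if (length(pos)) {
    if (is.unsorted(pos, strictly = TRUE))
      stop("deleterious positions must be strictly increasing", call. = FALSE)
    if (any(pos <= 0 | pos >= 1))
      stop("deleterious positions must lie in (0, 1)", call. = FALSE)
    n_z <- length(traits)
    if (any(pos * n_z == floor(pos * n_z)))
      stop("deleterious positions must not coincide with trait loci",
           call. = FALSE)
  }
  structure(list(traits = traits, pos = pos), class = "haplotype")
}

#' Trait phenotype of a diploid genotype
#'
#' Sums the additive allelic effects (+1/n_z per a allele, -1/n_z per A
#' allele) over both haplotypes, so `z` ranges over \[-2, 2\].
#'
#' @param hap1,hap2 Haplotypes with `n_z` trait alleles each.
#' @param n_z Number of trait loci.
#' @return Phenotype `z`.
#' @examples
#' h <- haplotype(rep(1L, 5))
#' trait_phenotype(h, h, 5) # 2
#' @export
trait_phenotype <- function(hap1, hap2, n_z) {
  if (length(hap1$traits) != n_z || length(hap2$traits) != n_z)
    stop("haplotypes must carry exactly n_z trait alleles", call. = FALSE)
  (sum(hap1$traits) + sum(hap2$traits)) / n_z
}

#' Logistic map from phenotype to selfing rate
#'
#' `alpha = 1 / (1 + exp(-k (z - z_c)))`: strictly increasing in `z` for
#' `k > 0` and exactly 0.5 at `z = z_c`.
#'
#' @param z Trait phenotype (vectorized).
#' @param k Steepness.
#' @param z_c Midpoint phenotype where `alpha = 0.5`.
#' @return Selfing rate(s) in (0, 1).
#' @examples
#' selfing_rate(0, k = 3, z_c = 0) # 0.5
#' @export
selfing_rate <- function(z, k, z_c) {
  stopifnot(is.finite(k))
  1 / (1 + exp(-k * (z - z_c)))
}

#' Stabilizing-selection viability
#'
#' Gaussian stabilizing selection on the selfing-rate trait,
#' `w1(z) = exp(-lambda z^2)`, maximal at `z = 0`.
#'
#' @param z Trait phenotype (vectorized).
#' @param lambda Selection strength (>= 0).
#' @return Viability in (0, 1\].
#' @export
viability_fitness <- function(z, lambda) {
  stopifnot(lambda >= 0)
  exp(-lambda * z^2)
}

#' Multiplicative fitness of deleterious mutations
#'
#' `w2 = (1 - h s)^n_het * (1 - s)^n_hom` across heterozygous and homozygous
#' deleterious mutations with shared selection coefficient `s` and dominance
#' `h`.
#'
#' @param n_het,n_hom Counts of heterozygous / homozygous deleterious
#'   mutations (vectorized).
#' @param s Selection coefficient in \[0, 1\].
#' @param h Dominance coefficient in \[0, 1\].
#' @return Fitness component in \[0, 1\].
#' @examples
#' deleterious_fitness(10, 2, s = 0.1, h = 0.2)
#' @export
deleterious_fitness <- function(n_het, n_hom, s, h) {
  stopifnot(all(n_het >= 0), all(n_hom >= 0), s >= 0, s <= 1, h >= 0, h <= 1)
  (1 - h * s)^n_het * (1 - s)^n_hom
}

#' Zygosity bookkeeping for deleterious mutations
#'
#' Counts deleterious mutations by zygosity from the two position sets:
#' homozygous = shared positions, heterozygous = symmetric difference. The
#' homozygosity fraction is `n_hom / (n_hom + n_het)`, defined as 0 for a
#' mutation-free genotype.
#'
#' @param hap1,hap2 Haplotypes.
#' @return List with `n_het`, `n_hom`, and `homozygosity`.
#' @examples
#' a <- haplotype(rep(1L, 4), c(0.15, 0.33))
#' b <- haplotype(rep(1L, 4), c(0.33, 0.61))
#' zygosity_counts(a, b) # 2 het, 1 hom, fraction 1/3
#' @export
zygosity_counts <- function(hap1, hap2) {
  n_hom <- length(intersect(hap1$pos, hap2$pos))
  n_het <- length(hap1$pos) + length(hap2$pos) - 2L * n_hom
  tot <- n_het + n_hom
  list(n_het = n_het, n_hom = n_hom,
       homozygosity = if (tot > 0) n_hom / tot else 0)
}

#' Assemble an individual from two haplotypes
#'
#' Computes every derived field of the model: phenotype `z`, selfing rate
#' `alpha = logistic(z)`, zygosity counts, viability `w1`, deleterious
#' fitness `w2`, and total fitness `w = w1 * w2`.
#'
#' @param hap1,hap2 Haplotypes.
#' @param params A [sim_params()] object.
#' @return Object of class `individual`.
#' @export
new_individual <- function(hap1, hap2, params) {
  z <- trait_phenotype(hap1, hap2, params$n_z)
  zc <- zygosity_counts(hap1, hap2)
  w1 <- viability_fitness(z, params$lambda)
  w2 <- deleterious_fitness(zc$n_het, zc$n_hom, params$s, params$h)
  structure(list(hap1 = hap1, hap2 = hap2, z = z,
                 alpha = selfing_rate(z, params$k, params$z_c),
                 n_het = zc$n_het, n_hom = zc$n_hom,
                 homozygosity = zc$homozygosity,
                 w1 = w1, w2 = w2, w = w1 * w2),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("individual: z = %.4g, alpha = %.4g, n_het = %d, n_hom = %d, w = %.4g\n",
              x$z, x$alpha, x$n_het, x$n_hom, x$w))
  invisible(x)
}
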