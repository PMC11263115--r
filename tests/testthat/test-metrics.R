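test_that("family assay of a mutation-free population shows no inbreeding depression", {
  set.seed(61)
  p <- toy_params(N = 30, U = 0, U_z = 0.2)
  pop <- initialize_population(p)
  assay <- family_assay(pop, p)
  expect_identical(nrow(assay), p$N)
  expect_true(all(assay$w_self == 1))
  expect_true(all(assay$w_out == 1))
  expect_true(all(assay$family_id == 0))
  expect_identical(population_id(assay), 0)
})

test_that("assay offspring fitness follows Mendelian expectations for one het mutation", {
  # focal adult het at one site in an otherwise mutation-free population:
  # E[w_self] = 1/4 + (1 - hs)/2 + (1 - s)/4, E[w_out] = 1 - hs/2
  s <- 0.4; h <- 0.25
  p <- toy_params(N = 20, U = 0, U_z = 0, s = s, h = h)
  carrier <- toy_individual(p, pos1 = 0.45)
  clean <- toy_individual(p)
  pop <- as_population(c(list(carrier), rep(list(clean), p$N - 1)))
  set.seed(62)
  n <- 4000
  ws <- numeric(n); wo <- numeric(n)
  for (i in seq_len(n)) {
    assay <- family_assay(pop, p)
    ws[i] <- assay$w_self[1]
    wo[i] <- assay$w_out[1]
  }
  e_self <- 0.25 + 0.5 * (1 - h * s) + 0.25 * (1 - s)
  e_out <- 1 - h * s / 2
  expect_lt(abs(mean(ws) - e_self), 3 * sd(ws) / sqrt(n))
  expect_lt(abs(mean(wo) - e_out), 3 * sd(wo) / sqrt(n))
})

test_that("population-level ID is the ratio of means, not the mean family ID", {
  assay <- data.frame(w_self = c(0.6, 0.6), w_out = c(0.8, 0.8))
  expect_equal(population_id(assay), 0.25)
  expect_identical(population_id(data.frame(w_self = c(0.3, 0.9),
                                            w_out = c(0.3, 0.9))), 0)
  expect_identical(population_id(data.frame(w_self = c(0, 0),
                                            w_out = c(0.5, 0.7))), 1)
  skewed <- data.frame(w_self = c(0.1, 0.8), w_out = c(0.2, 0.8))
  fam_mean <- mean(1 - skewed$w_self / skewed$w_out)
  expect_false(isTRUE(all.equal(population_id(skewed), fam_mean)))
  expect_error(population_id(data.frame(w_self = 0, w_out = 0)), "zero")
})

test_that("association summary matches direct Pearson and OLS computations", {
  p <- toy_params(N = 4)
  alpha <- c(0.1, 0.3, 0.6, 0.8)
  w_out <- c(0.7, 0.8, 0.85, 0.9)
  w_self <- c(0.65, 0.6, 0.5, 0.45)
  inds <- lapply(seq_along(alpha), function(i) toy_individual(p))
  assay <- data.frame(alpha = alpha, w_self = w_self, w_out = w_out,
                      family_id = 1 - w_self / w_out)
  asc <- association_summary(as_population(inds), assay = assay)
  expect_equal(asc$pearson[["wout"]], stats::cor(alpha, w_out),
               tolerance = 1e-12)
  expect_equal(asc$pearson[["wself"]], stats::cor(alpha, w_self),
               tolerance = 1e-12)
  expect_equal(asc$slope[["wout"]],
               unname(stats::coef(stats::lm(w_out ~ alpha))[2]),
               tolerance = 1e-12)
  expect_equal(asc$rho_self, asc$slope[["wself"]])
  expect_equal(asc$alpha_bar, mean(alpha))
  expect_equal(asc$V_alpha, mean((alpha - mean(alpha))^2))
  # hand-computed Pearson for the 4-family toy table
  # hand computation: cov = 0.019375, V_alpha = 0.0725, V_wout = 0.00546875
  expect_equal(asc$pearson[["wout"]], 0.019375 / sqrt(0.0725 * 0.00546875),
               tolerance = 1e-12)

  # exact linear relation gives r = 1
  lin <- data.frame(alpha = alpha, w_self = 1 - alpha, w_out = 0.2 + alpha,
                    family_id = NA)
  lin$family_id <- 1 - lin$w_self / lin$w_out
  asc_lin <- association_summary(as_population(inds), assay = lin)
  expect_equal(asc_lin$pearson[["wout"]], 1, tolerance = 1e-12)
  expect_equal(asc_lin$pearson[["wself"]], -1, tolerance = 1e-12)

  # pearson option routes the correlation into rho
  asc_p <- association_summary(as_population(inds), assay = assay,
                               rho = "pearson")
  expect_equal(asc_p$rho_out, asc$pearson[["wout"]])
})

test_that("zero selfing-rate variance flags correlations as undefined", {
  p <- toy_params(N = 4)
  inds <- replicate(4, toy_individual(p), simplify = FALSE)
  assay <- data.frame(alpha = rep(0.4, 4), w_self = c(0.5, 0.6, 0.7, 0.8),
                      w_out = c(0.9, 0.8, 0.85, 0.95))
  assay$family_id <- 1 - assay$w_self / assay$w_out
  asc <- association_summary(as_population(inds), assay = assay)
  expect_true(asc$undefined)
  expect_true(all(is.na(asc$pearson[c("wout", "wself")])))
  expect_true(all(is.na(asc$slope[c("wout", "wself")])))
  expect_error(association_summary(as_population(inds[1:2]),
                                   assay = assay[1:2, ]), "3 families")
})

test_that("families with zero outcrossed fitness are dropped and counted", {
  p <- toy_params(N = 5)
  inds <- replicate(5, toy_individual(p), simplify = FALSE)
  assay <- data.frame(alpha = c(0.1, 0.2, 0.5, 0.7, 0.9),
                      w_self = c(0.5, 0.4, 0.3, 0.2, 0.1),
                      w_out = c(0.9, 0, 0.8, 0, 0.6))
  assay$family_id <- ifelse(assay$w_out > 0, 1 - assay$w_self / assay$w_out, NA)
  asc <- association_summary(as_population(inds), assay = assay)
  expect_identical(asc$n_dropped_family_id, 2L)
  keep <- assay$w_out > 0
  expect_equal(asc$pearson[["family_id"]],
               stats::cor(assay$alpha[keep], assay$family_id[keep]),
               tolerance = 1e-12)
})

test_that("slope times variance reproduces the covariance", {
  set.seed(63)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- runif(n)
    y <- runif(n) + 0.5 * x
    slope <- selfID:::slope_or_na(x, y)
    expect_equal(slope * var_pop(x), selfID:::cov_pop(x, y), tolerance = 1e-12)
    # and the population moments agree with the n-1 estimators rescaled
    expect_equal(var_pop(x), stats::var(x) * (n - 1) / n, tolerance = 1e-12)
  }
})

test_that("selfing-rate variance respects its 0.25 ceiling", {
  expect_identical(var_pop(rep(c(0, 1), 50)), 0.25)
  expect_identical(var_pop(rep(c(0, 1), 3)), 0.25)
  set.seed(64)
  for (i in 1:50) expect_lte(var_pop(runif(20)), 0.25)
  # uneven two-point splits stay strictly below the bound
  expect_lt(var_pop(c(0, 0, 1)), 0.25)
})

test_that("homozygosity is binned over half-open equal-width alpha bins", {
  p <- toy_params(N = 3, k = 50)
  mk <- function(trait, pos1, pos2) new_individual(
    haplotype(rep(trait, p$n_z), pos1), haplotype(rep(trait, p$n_z), pos2), p)
  # alpha = 1 (traits +1, k = 50) and alpha ~ 0 (traits -1)
  i1 <- mk(1L, c(0.15, 0.25), c(0.25, 0.35))   # homozygosity 1/3
  i2 <- mk(1L, c(0.41, 0.55), c(0.41, 0.55))   # homozygosity 1
  i3 <- mk(-1L, 0.15, numeric(0))              # homozygosity 0
  prof <- binned_homozygosity(as_population(list(i1, i2, i3)), n_bins = 10)
  expect_identical(nrow(prof), 10L)
  # alpha = 1 falls in the last (right-closed) bin; mean of 1/3 and 1
  expect_equal(prof$mean_homozygosity[10], mean(c(1 / 3, 1)))
  expect_identical(prof$n[10], 2L)
  # alpha ~ 0 falls in the first bin
  expect_identical(prof$n[1], 1L)
  expect_equal(prof$mean_homozygosity[1], 0)
  expect_true(all(is.na(prof$mean_homozygosity[2:9])))
  # bin edges are half-open [lo, hi): alpha exactly at an edge goes up
  p2 <- toy_params(N = 2, k = 3, z_c = 0)
  # z = 0 gives alpha = 0.5 exactly, the edge between bins 5 and 6
  bal <- new_individual(haplotype(rep(c(1L, -1L), 5)),
                        haplotype(rep(c(1L, -1L), 5)), p2)
  prof2 <- binned_homozygosity(as_population(list(bal, bal)), n_bins = 10)
  expect_identical(prof2$n[6], 2L)
  expect_identical(prof2$n[5], 0L)
})

test_that("equilibrium summaries average the trailing window and count NAs", {
  rec <- data.frame(generation = 1:100, alpha_bar = (1:100) / 100,
                    delta0 = c(rep(NA, 50), rep(0.2, 50)))
  eq <- summarize_equilibrium(rec, window = 10)
  expect_equal(eq$means[["alpha_bar"]], 0.955)
  expect_identical(eq$n_used[["alpha_bar"]], 10L)

  rec2 <- data.frame(generation = 1:100, x = 1:100)
  expect_equal(summarize_equilibrium(rec2, 10)$means[["x"]], 95.5)
  expect_equal(summarize_equilibrium(rec2, 100)$means[["x"]], 50.5)
  expect_error(summarize_equilibrium(rec2, 101), "window")

  const <- data.frame(generation = 1:5, x = rep(3.3, 5))
  expect_equal(summarize_equilibrium(const, 3)$means[["x"]], 3.3)

  # NA entries are excluded with counts reported
  rec3 <- data.frame(generation = 1:10, y = c(rep(NA_real_, 9), 7))
  eq_na <- summarize_equilibrium(rec3, 10)
  expect_equal(eq_na$means[["y"]], 7)
  expect_identical(eq_na$n_used[["y"]], 1L)
})

test_that("metrics_record agrees with standalone metric functions", {
  set.seed(65)
  p <- toy_params(N = 40, U = 0.8, U_z = 0.2, s = 0.2, lambda = 0.5,
                  generations = 15, window = 5, seed = 65)
  sim <- run_simulation(p)
  pop <- sim$final_population
  rec <- metrics_record(pop, p, assay = FALSE)
  alpha <- vapply(pop$individuals, `[[`, numeric(1), "alpha")
  expect_equal(rec$alpha_bar, mean(alpha))
  expect_equal(rec$V_alpha, var_pop(alpha))
  expect_true(is.na(rec$delta0))
  set.seed(66)
  assay <- family_assay(pop, p)
  rec2 <- metrics_record(pop, p, assay = assay)
  expect_equal(rec2$delta0, population_id(assay))
  asc <- association_summary(pop, assay = assay)
  expect_equal(rec2$corr_alpha_wself, asc$pearson[["wself"]])
  expect_equal(rec2$slope_alpha_wout, asc$slope[["wout"]])
})
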