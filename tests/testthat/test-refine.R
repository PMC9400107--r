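# Refinement unit tests run on a reduced resolution cutoff to stay quick;
# the full-resolution recovery of the parametrization protocol lives in
# test-acceptance.R.

test_that("refinement of an exact model from the truth is a fixed point", {
  model <- water_model(a = 12)
  refl <- generate_reflections(12, 0.6)
  target <- structure_factors(model, refl)
  res <- refine_parameters(target, model, refl,
                           refinable = c("p_val", "kappa", "plm"))
  expect_lt(res$r_factor, 1e-12)
  expect_lt(max(abs(res$par$shift)), 1e-9)
  expect_true(res$converged)
})

test_that("perturbed water parameters are recovered from a neutral start", {
  a <- 12
  truth <- water_model(a = a)
  refl <- generate_reflections(a, 0.7)
  target <- structure_factors(truth, refl)
  start <- water_model(a = a, perturbed = FALSE)
  res <- refine_parameters(target, start, refl,
                           refinable = c("p_val", "kappa", "plm"))
  expect_true(res$converged)
  expect_lt(res$r_factor, 1e-8)
  for (i in 1:3) {
    pt <- truth$sites[[i]]$params
    pf <- res$model$sites[[i]]$params
    expect_equal(pf$p_val, pt$p_val, tolerance = 1e-3)
    expect_equal(pf$kappa, pt$kappa, tolerance = 1e-3)
    expect_equal(unclass(pf$plm), unclass(pt$plm), tolerance = 2e-3,
                 ignore_attr = TRUE)
  }
  # shared-kappa constraint: both hydrogens end at the identical value
  expect_identical(res$model$sites[[2L]]$params$kappa,
                   res$model$sites[[3L]]$params$kappa)
  # hydrogens carry only the bond-directed functions
  hp <- res$par[res$par$kind == "plm" & res$par$atom %in% 2:3, ]
  expect_true(all(hp$m == 0L & hp$l %in% 1:2))
})

test_that("analytic least-squares gradients match finite differences", {
  set.seed(31)
  model <- water_model(a = 10, kappa_prime = TRUE)
  refl <- generate_reflections(10, 0.35)
  table <- taamkit:::.param_table(model,
                                  c("p_val", "kappa", "kappa_prime",
                                    "plm"))
  pre <- taamkit:::.sf_precompute(model, refl)
  fcalc <- function(par) {
    m2 <- taamkit:::.apply_params(model, table, par)
    structure_factors(m2, refl)
  }
  J <- taamkit:::.sf_jacobian(model, refl, pre, table)
  p0 <- table$start
  for (j in seq_along(p0)) {
    h <- 1e-6
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    num <- (fcalc(pp) - fcalc(pm)) / (2 * h)
    scale <- max(abs(num), 1)
    expect_lt(max(abs(J[, j] - num)) / scale, 1e-5)
  }
})

test_that("releasing the shared hydrogen kappa cannot worsen the fit", {
  a <- 10
  truth <- water_model(a = a)
  refl <- generate_reflections(a, 0.5)
  # targets from slightly inequivalent hydrogens
  t2 <- truth
  t2$sites[[3L]]$params$kappa <- 1.18
  t2$kappa_groups <- 1:3
  target <- structure_factors(t2, refl)
  start_shared <- water_model(a = a, perturbed = FALSE)
  res_shared <- refine_parameters(target, start_shared, refl,
                                  refinable = c("p_val", "kappa", "plm"))
  start_free <- start_shared
  start_free$kappa_groups <- 1:3
  res_free <- refine_parameters(target, start_free, refl,
                                refinable = c("p_val", "kappa", "plm"))
  expect_lte(res_free$r_factor, res_shared$r_factor + 1e-12)
})

test_that("a rank-deficient parametrization is reported with its null space", {
  # kappa' of an atom with zero deformation populations is undetermined
  s <- molecular_structure("O", matrix(5, 1L, 3L))
  sites <- list(list(params = multipole_parameters(6, 1, 1, plm_zero()),
                     symmetry = "no"))
  model <- pseudoatom_model(s, a = 10, sites = sites)
  refl <- generate_reflections(10, 0.4)
  target <- structure_factors(model, refl)
  expect_error(refine_parameters(target, model, refl,
                                 refinable = c("p_val", "kappa_prime")),
               "rank-deficient.*kprime")
})
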