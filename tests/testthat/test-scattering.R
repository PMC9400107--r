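test_that("reflection generation enumerates the sphere exactly", {
  r <- generate_reflections(30, 1 / 60 + 1e-4)
  expect_equal(nrow(r$hkl), 6L)
  expect_setequal(apply(r$hkl, 1L, paste, collapse = ","),
                  c("1,0,0", "-1,0,0", "0,1,0", "0,-1,0", "0,0,1",
                    "0,0,-1"))
  expect_false(any(rowSums(abs(r$hkl)) == 0L))   # (0,0,0) excluded
  # monotone count in s_max
  n1 <- nrow(generate_reflections(10, 0.3)$hkl)
  n2 <- nrow(generate_reflections(10, 0.5)$hkl)
  n3 <- nrow(generate_reflections(10, 0.7)$hkl)
  expect_true(n1 <= n2 && n2 <= n3)
  # s convention: s = sqrt(h^2+k^2+l^2) / (2a), strictly below the cutoff
  rr <- generate_reflections(12, 0.8)
  expect_equal(rr$s, sqrt(rowSums(rr$hkl^2)) / 24)
  expect_true(all(rr$s > 0 & rr$s < 0.8))
})

test_that("form factors have the analytic limits and symmetries", {
  sph <- spherical_atom_density("O")
  rm_ <- radial_model("O")
  p <- multipole_parameters(6.3, 0.95, 1.1,
                            plm_set(plm_zero(), 1, 0, 0.1))
  # |h| -> 0 limit is P_val
  f0 <- atomic_form_factor(p, rm_, sph, c(1e-9, 0, 0))
  expect_equal(Re(f0), 6.3, tolerance = 1e-6)
  # monopole-only form factor is real everywhere
  pm <- multipole_parameters(6.3, 0.95, 1.1, plm_zero())
  sv <- matrix(rnorm(30), ncol = 3L)
  expect_equal(max(abs(Im(atomic_form_factor(pm, rm_, sph, sv)))), 0)
  # dipole term is imaginary (i^1) and odd in h
  pd <- multipole_parameters(0, 1, 1, plm_set(plm_zero(), 1, 0, 0.2))
  fd <- atomic_form_factor(pd, rm_, sph, rbind(c(0, 0, 0.5),
                                               c(0, 0, -0.5)))
  expect_equal(Re(fd), c(0, 0), tolerance = 1e-12)
  expect_equal(Im(fd[1L]), -Im(fd[2L]), tolerance = 1e-12)
  expect_error(atomic_form_factor(pd, radial_model("C", n_l = 0:4,
                                                   zeta = rep(6, 5)),
                                  sph, c(0, 0, 0.5)), NA)
})

test_that("a single monopole atom at the origin gives real F = f(|h|)", {
  s <- molecular_structure("O", matrix(0, 1L, 3L))
  sites <- list(list(params = multipole_parameters(6, 0.97, 1,
                                                   plm_zero())))
  model <- pseudoatom_model(s, a = 10, sites = sites)
  refl <- generate_reflections(10, 0.5)
  FF <- structure_factors(model, refl)
  expect_equal(max(abs(Im(FF))), 0, tolerance = 1e-12)
  f_ref <- 6 * valence_form_factor(spherical_atom_density("O"), refl$H,
                                   0.97)
  expect_equal(Re(FF), f_ref, tolerance = 1e-10)
})

test_that("translating the model by (1/2,1/2,1/2) flips odd reflections", {
  model <- water_model(a = 12)
  refl <- generate_reflections(12, 0.45)
  F1 <- structure_factors(model, refl)
  m2 <- model
  m2$structure$xyz <- sweep(m2$structure$xyz, 2L, rep(6, 3L), "+")
  for (i in seq_along(m2$sites))
    m2$sites[[i]]$frame$origin <- m2$sites[[i]]$frame$origin + rep(6, 3L)
  F2 <- structure_factors(m2, refl)
  parity <- (-1)^rowSums(refl$hkl)
  expect_equal(F2, F1 * parity, tolerance = 1e-10)
})

test_that("structure factors match a numerical Fourier transform of the density", {
  a <- 8; n <- 64
  model <- water_model(a = a, kappa_prime = TRUE)
  refl <- generate_reflections(a, 0.4)
  Fc <- structure_factors(model, refl)
  g <- (seq_len(n) - 1) / n * a
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  rho <- numeric(nrow(pts))
  for (s in model$sites) {
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      fr <- s$frame
      fr$origin <- fr$origin + a * c(sx, sy, sz)
      rho <- rho + hc_density(s$params, s$sph, s$radial, fr, pts,
                              include_core = FALSE)
    }
  }
  Fg <- fft(array(rho, dim = c(n, n, n)), inverse = TRUE) * (a / n)^3
  idx <- function(h) ((h %% n) + 1L)
  Ff <- complex(length(Fc))
  for (r in seq_len(nrow(refl$hkl)))
    Ff[r] <- Fg[idx(refl$hkl[r, 1L]), idx(refl$hkl[r, 2L]),
                idx(refl$hkl[r, 3L])]
  expect_lt(max(Mod(Ff - Fc)) / max(Mod(Fc)), 1e-3)
})
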