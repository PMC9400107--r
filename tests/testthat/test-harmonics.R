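test_that("density-normalized harmonics have the documented values and norms", {
  expect_equal(real_spherical_harmonic(0, 0, c(0, 0, 1)), 1 / (4 * pi))
  expect_equal(real_spherical_harmonic(1, 0, c(0, 0, 1)), 1 / pi)
  expect_equal(real_spherical_harmonic(1, 0, c(0, 0, -1)), -1 / pi)
  # cosine-type d_11 vanishes on its nodal plane
  expect_equal(real_spherical_harmonic(1, 1, c(0, 1, 0)), 0)
  expect_error(real_spherical_harmonic(2, 3, c(0, 0, 1)), "m")

  # quadrature check of the normalization convention on a sample of (l, m)
  for (lm in list(c(0, 0), c(1, 0), c(2, 2), c(3, -1), c(4, 4), c(4, 0))) {
    l <- lm[1L]; m <- lm[2L]
    val <- sphere_integral(function(z, phi) {
      st <- sqrt(1 - z^2)
      u <- cbind(st * cos(phi), st * sin(phi), z)
      if (l == 0L) real_spherical_harmonic(l, m, u)
      else abs(real_spherical_harmonic(l, m, u))
    }, n_theta = 2000L, n_phi = 600L)
    expect_equal(val, if (l == 0L) 1 else 2, tolerance = 1e-3)
  }
})

test_that("rotate_plm satisfies the grid-equality definition", {
  set.seed(41)
  for (rep in 1:5) {
    R <- random_rotation_matrix()
    p <- random_plm()
    pr <- rotate_plm(p, R)
    u <- random_directions(50)
    expect_equal(plm_density(pr, u), plm_density(p, u %*% R),
                 tolerance = 1e-10)
  }
  # identity and l = 0 invariance
  p <- random_plm()
  expect_equal(rotate_plm(p, diag(3)), p)
  R <- random_rotation_matrix()
  expect_equal(plm_get(rotate_plm(p, R), 0, 0), plm_get(p, 0, 0))
})

test_that("rotate_plm is a homomorphism and rejects improper rotations", {
  set.seed(42)
  for (rep in 1:5) {
    R1 <- random_rotation_matrix(); R2 <- random_rotation_matrix()
    p <- random_plm()
    expect_equal(rotate_plm(p, R1 %*% R2),
                 rotate_plm(rotate_plm(p, R2), R1), tolerance = 1e-10)
  }
  expect_error(rotate_plm(random_plm(), diag(c(1, 1, -1))), "improper")
})

test_that("90-degree z rotation exchanges the l = 1 in-plane populations", {
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3L, 3L)  # +90 about z
  p <- plm_set(plm_zero(), 1, 1, 0.7)
  pr <- rotate_plm(p, Rz)
  u <- random_directions(50)
  expect_equal(plm_density(pr, u), plm_density(p, u %*% Rz),
               tolerance = 1e-12)
  # the cosine population moves entirely into the sine slot
  expect_equal(abs(plm_get(pr, 1, -1)), 0.7, tolerance = 1e-12)
  expect_equal(plm_get(pr, 1, 1), 0, tolerance = 1e-12)
})

test_that("allowed_indices reproduces hand-derived selection rules", {
  key <- function(idx) paste(idx[, "l"], idx[, "m"], sep = ",")
  expect_length(key(allowed_indices("no", 4)), 25L)
  # mm2: cosine terms with even m survive C2z and both vertical mirrors
  expect_setequal(key(allowed_indices("mm2", 4)),
                  c("0,0", "1,0", "2,0", "2,2", "3,0", "3,2", "4,0", "4,2",
                    "4,4"))
  # 3m: m = 0 plus cosine m = 3
  expect_setequal(key(allowed_indices("3m", 4)),
                  c("0,0", "1,0", "2,0", "3,0", "3,3", "4,0", "4,3"))
  # mirror through xz: all cosine-type terms
  m_idx <- allowed_indices("m", 4)
  expect_true(all(m_idx[, "m"] >= 0L))
  expect_length(key(m_idx), 15L)
  # cylindrical: axial terms only; centrosymmetric cylinder: even l
  expect_setequal(key(allowed_indices("cyl", 4)),
                  c("0,0", "1,0", "2,0", "3,0", "4,0"))
  expect_setequal(key(allowed_indices("cylinf", 4)),
                  c("0,0", "2,0", "4,0"))
  expect_error(allowed_indices("q2q", 4), "point-group")
})

test_that("the symmetry projector is idempotent", {
  for (g in point_group_symbols()) {
    for (l in 1:4) {
      P <- taamkit:::symmetry_projector_block(l, g)
      expect_equal(P %*% P, P, tolerance = 1e-10)
    }
  }
})

test_that("projected densities are invariant under all group operations", {
  set.seed(43)
  u <- random_directions(100)
  for (g in point_group_symbols()) {
    p <- project_plm(random_plm(), g)
    f0 <- plm_density(p, u)
    for (op in taamkit:::point_group_elements(g)) {
      expect_equal(plm_density(p, u %*% op), f0, tolerance = 1e-10,
                   label = paste("group", g))
    }
  }
})

test_that("unicode and alias point-group spellings normalize", {
  expect_identical(normalize_point_group("43m"), "-43m")
  expect_identical(normalize_point_group("1"), "no")
  expect_identical(normalize_point_group("mm2"), "mm2")
})
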