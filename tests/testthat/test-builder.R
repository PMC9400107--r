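test_that("reorientation leaves same-frame instances unchanged", {
  p <- multipole_parameters(4.1, 0.98, 0.95, random_plm())
  ins <- structure(list(params = p, frame = local_frame()),
                   class = "parameter_instance")
  out <- reorient_instance(ins, local_frame())
  expect_equal(out$plm, p$plm, tolerance = 1e-14)
  expect_equal(out$p_val, p$p_val)
  expect_equal(out$kappa, p$kappa)
})

test_that("frames differing by the local 3-fold give identical reoriented populations", {
  # populations with 3m symmetry are invariant under 120-degree rotation
  set.seed(17)
  plm <- project_plm(random_plm(), "3m")
  C3 <- taamkit:::.rot_axis(c(0, 0, 1), 2 * pi / 3)
  p1 <- multipole_parameters(4, 1, 1, plm)
  p2 <- multipole_parameters(4, 1, 1, rotate_plm(plm, t(C3)))
  i1 <- structure(list(params = p1, frame = local_frame()),
                  class = "parameter_instance")
  i2 <- structure(list(params = p2, frame = local_frame(rotation = C3)),
                  class = "parameter_instance")
  r1 <- reorient_instance(i1, local_frame())
  r2 <- reorient_instance(i2, local_frame())
  expect_equal(r1$plm, r2$plm, tolerance = 1e-10)
})

test_that("reorientation preserves the deformation density norm per l", {
  # rotation is unitary on the function space; the conserved quantity is
  # the L2 norm of the deformation density, i.e. sum_m (c_lm P_lm)^2 with
  # c_lm the density-normalization constants (the bare sum of squared
  # populations is not invariant because the d_lm norms differ across |m|)
  set.seed(18)
  p <- multipole_parameters(4, 1, 1, random_plm())
  R <- random_rotation_matrix()
  ins <- structure(list(params = p, frame = local_frame(rotation = R)),
                   class = "parameter_instance")
  out <- reorient_instance(ins, local_frame())
  l2 <- function(plm, l) {
    acc <- 0
    for (m in seq.int(-l, l)) {
      c_lm <- taamkit:::.dlm_norm[[paste0(l, "_", abs(m))]]
      acc <- acc + (c_lm * plm_get(plm, l, m))^2
    }
    acc
  }
  for (l in 1:4)
    expect_equal(l2(out$plm, l), l2(p$plm, l), tolerance = 1e-10)
})

test_that("averaging gives the textbook mean and sample standard deviation", {
  e <- fixture_bank("minimal6")$entries[[1L]]
  mk <- function(pv) structure(
    list(params = multipole_parameters(pv, 0.99, 0.92,
                                       e$params$plm_mean),
         frame = local_frame()), class = "parameter_instance")
  avg <- average_type(list(mk(4.0), mk(4.2)), e, reorient = FALSE)
  expect_equal(avg$params$p_val[1L], 4.1)
  expect_equal(avg$params$p_val[2L], sd(c(4.0, 4.2)))
  expect_equal(avg$params$p_val[3L], 2)
  # identical instances: all ssd zero
  avg2 <- average_type(list(mk(4.0), mk(4.0), mk(4.0)), e,
                       reorient = FALSE)
  expect_equal(avg2$params$p_val[2L], 0)
  expect_equal(max(avg2$params$plm_ssd), 0)
  expect_error(average_type(list(), e), "zero instances")
})

test_that("symmetry-forbidden populations are zeroed by averaging", {
  e <- fixture_bank("minimal6")$entries[[5L]]   # water O, mm2
  plm <- plm_set(e$params$plm_mean, 2, -1, 0.02)  # small forbidden leak
  ins <- structure(list(params = multipole_parameters(6.2, 1, 1, plm),
                        frame = local_frame()),
                   class = "parameter_instance")
  avg <- average_type(list(ins, ins), e, reorient = FALSE)
  expect_equal(plm_get(avg$params$plm_mean, 2, -1), 0)
  expect_equal(plm_get(avg$params$plm_mean, 2, 2),
               plm_get(plm, 2, 2))
})

test_that("averaging commutes with a common rotation and is frame-independent", {
  set.seed(19)
  e <- fixture_bank("minimal6")$entries[[1L]]
  ins <- make_noisy_instances(e, 12, sigma = list(p_val = 0.05,
                                                  plm = 0.02), seed = 4L)
  avg1 <- average_type(ins, e)
  # rotate every instance frame by the same R: the averaged entry (which
  # reorients into the type frame) must be unchanged
  R <- random_rotation_matrix()
  ins2 <- lapply(ins, function(i) {
    i$frame <- local_frame(rotation = i$frame$rotation %*% R)
    i$params <- multipole_parameters(i$params$p_val, i$params$kappa,
                                     i$params$kappa_prime,
                                     rotate_plm(i$params$plm, t(R)),
                                     l_max = i$params$l_max)
    i
  })
  avg2 <- average_type(ins2, e)
  expect_equal(avg2$params$plm_mean, avg1$params$plm_mean,
               tolerance = 1e-10)
  expect_equal(avg2$params$plm_ssd, avg1$params$plm_ssd,
               tolerance = 1e-10)
  # ssd invariant under instance reordering
  avg3 <- average_type(rev(ins), e)
  expect_equal(avg3$params$plm_ssd, avg1$params$plm_ssd,
               tolerance = 1e-12)
  expect_equal(avg3$params$p_val, avg1$params$p_val, tolerance = 1e-12)
})

test_that("quality verdicts flag exactly the over-threshold parameters", {
  e <- fixture_bank("minimal6")$entries[[1L]]
  e$params$kappa[2L] <- 0.02
  qc <- quality_check(e)
  expect_false(qc$pass)
  expect_equal(qc$violations$parameter, "kappa")
  expect_equal(qc$violations$ssd, 0.02)
  expect_equal(qc$violations$threshold, 0.01)
  # P_lm just over the 0.05 e bound
  e2 <- fixture_bank("minimal6")$entries[[1L]]
  e2$params$plm_ssd <- plm_set(e2$params$plm_ssd, 3, 3, 0.051)
  qc2 <- quality_check(e2)
  expect_false(qc2$pass)
  expect_match(qc2$violations$parameter, "plm\\(3,\\+3\\)")
  # all-zero ssd passes; loose entries pass with violations listed
  e3 <- fixture_bank("minimal6")$entries[[1L]]
  expect_true(quality_check(e3)$pass)
  e2$allow_loose <- TRUE
  qc3 <- quality_check(e2)
  expect_true(qc3$pass)
  expect_equal(nrow(qc3$violations), 1L)
})

test_that("q-kappa regression recovers exact linear relations", {
  mk_entry <- function(id, pv) {
    e <- taamkit:::.entry_generic_C4()
    e$type_id <- id
    e$params$p_val[1L] <- pv
    e$params$kappa[1L] <- 1 - 0.1 * (4 - pv)   # kappa = 1 - 0.1 q
    e$params$kappa_prime[1L] <- 0.9            # constant
    e
  }
  b <- bank(lapply(1:5, function(i) mk_entry(paste0("C", i), 3.6 + 0.2 * i)))
  res <- q_kappa_analysis(b)
  rk <- res[res$class == "C" & res$parameter == "kappa", ]
  expect_equal(rk$slope, -0.1, tolerance = 1e-12)
  expect_equal(rk$r_squared, 1, tolerance = 1e-12)
  rkp <- res[res$class == "C" & res$parameter == "kappa_prime", ]
  expect_equal(rkp$r_squared, 0, tolerance = 1e-12)
  # two entries are not enough for a class
  b2 <- bank(lapply(1:2, function(i) mk_entry(paste0("C", i), 3.8 + 0.2 * i)))
  expect_error(q_kappa_analysis(b2), "entries")
})
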