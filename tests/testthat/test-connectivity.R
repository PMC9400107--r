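test_that("bond detection follows covalent radii plus slack", {
  radii <- c(C = 0.77, H = 0.31)
  s <- molecular_structure(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)))
  s <- build_connectivity(s, radii)
  expect_equal(nrow(s$bonds), 1L)     # 1.09 <= 0.77 + 0.31 + 0.4
  s2 <- molecular_structure(c("C", "H"), rbind(c(0, 0, 0), c(5, 0, 0)))
  s2 <- build_connectivity(s2, radii)
  expect_equal(nrow(s2$bonds), 0L)
  s3 <- molecular_structure(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_error(build_connectivity(s3), "overlapping")
})

test_that("bridging hydrogens keep only their shortest bond", {
  s <- molecular_structure(c("O", "H", "O"),
                           rbind(c(0, 0, 0), c(1.10, 0, 0),
                                 c(2.35, 0, 0)))
  s <- build_connectivity(s)
  expect_equal(attr(s$bonds, "multivalent_hydrogens"), "H1")
  hb <- s$bonds[s$bonds[, 1L] == 2L | s$bonds[, 2L] == 2L, , drop = FALSE]
  expect_equal(nrow(hb), 1L)
  expect_setequal(as.integer(hb), c(1L, 2L))  # the 1.10 A bond survives
})

test_that("ring perception finds the aromatic and small rings", {
  benz <- make_molecule("benzene")
  expect_length(benz$rings, 1L)
  expect_equal(benz$rings[[1L]]$size, 6L)
  expect_true(benz$rings[[1L]]$planar)
  cp <- make_molecule("cyclopropane")
  expect_length(cp$rings, 1L)
  expect_equal(cp$rings[[1L]]$size, 3L)
})

test_that("naphthalene bridgeheads sit in two six-rings", {
  nap <- make_molecule("naphthalene")
  expect_length(nap$rings, 2L)
  d <- compute_descriptors(nap)
  n_rings <- vapply(d, function(x) nrow(x$rings), 0L)
  carbons <- which(nap$z == 6L)
  expect_equal(sum(n_rings[carbons] == 2L), 2L)   # the two bridgeheads
  expect_equal(sum(n_rings[carbons] == 1L), 8L)
})

test_that("single cycles of every size are perceived as exactly one ring", {
  # oracle: a regular n-gon has cycle-space dimension 1, so SSSR must
  # return the full cycle and nothing else
  for (n in 3:9) {
    phi <- 2 * pi * (seq_len(n) - 1L) / n
    r <- 1.5 / (2 * sin(pi / n))    # side length 1.5 A
    s <- molecular_structure(rep("C", n), cbind(r * cos(phi),
                                                r * sin(phi), 0))
    s <- perceive_rings(build_connectivity(s))
    expect_length(s$rings, 1L)
    expect_equal(s$rings[[1L]]$size, n)
  }
})

test_that("group planarity is defined by the 0.1 A least-squares criterion", {
  benz <- make_molecule("benzene")
  d <- compute_descriptors(benz)
  expect_true(all(vapply(which(benz$z == 6L),
                         function(i) isTRUE(d[[i]]$planar), TRUE)))
  met <- make_molecule("methane")
  dm <- compute_descriptors(met)
  expect_false(dm[[1L]]$planar)           # tetrahedral carbon
  expect_true(is.na(dm[[2L]]$planar))     # hydrogen: undefined
  nm <- make_molecule("nitromethane")
  dn <- compute_descriptors(nm)
  expect_true(dn[[1L]]$planar)            # nitro nitrogen
  expect_equal(nrow(dn[[1L]]$rings), 0L)
})

test_that("cluster growth expands periodic chains and is monotone", {
  w <- make_molecule("water")
  expect_equal(length(grow_cluster(w, 3L)$z), 3L)  # isolated molecule
  ch <- make_molecule("p1_chain")
  n1 <- length(grow_cluster(ch, 1L)$z)
  n2 <- length(grow_cluster(ch, 2L)$z)
  n3 <- length(grow_cluster(ch, 3L)$z)
  expect_equal(sum(grow_cluster(ch, 2L)$in_asu), 3L)
  expect_true(n1 <= n2 && n2 <= n3)
  expect_gt(n1, 3L)   # images joined
  # asymmetric-unit carbon reaches its full coordination
  cl <- grow_cluster(ch, 2L)
  d <- compute_descriptors(cl)
  i <- which(cl$in_asu & cl$z == 6L)
  expect_equal(d[[i]]$n_neighbors, 4L)
  expect_error(grow_cluster(ch, 0L), "depth")
})

test_that("the fixture bank needs a two-shell cluster", {
  expect_equal(bank_depth(fixture_bank("minimal6")), 2L)
})

test_that("X-H normalization moves hydrogens along the bond to the table value", {
  s <- molecular_structure(c("O", "H"),
                           rbind(c(0, 0, 0), c(0.82, 0, 0)))
  s <- build_connectivity(s)
  s2 <- normalize_xh_bonds(s)
  expect_equal(drop(s2$xyz[2L, ]), c(0.983, 0, 0), tolerance = 1e-12)
  expect_equal(s2$xyz[1L, ], s$xyz[1L, ])  # heavy atom unmoved
  # already at the table value: unchanged
  s3 <- normalize_xh_bonds(s2)
  expect_equal(s3$xyz, s2$xyz)
  # methyl C-H goes to the sp3 table entry, direction preserved
  eth <- make_molecule("ethane")
  v_old <- eth$xyz[3L, ] - eth$xyz[1L, ]
  e2 <- normalize_xh_bonds(eth)
  v_new <- e2$xyz[3L, ] - e2$xyz[1L, ]
  expect_equal(sqrt(sum(v_new^2)), 1.083, tolerance = 1e-12)
  expect_equal(v_new / sqrt(sum(v_new^2)), v_old / sqrt(sum(v_old^2)),
               tolerance = 1e-12)
  expect_equal(e2$xyz[1:2, ], eth$xyz[1:2, ])
})

test_that("connectivity is symmetric and deterministic", {
  nap <- make_molecule("naphthalene")
  b1 <- build_connectivity(nap)$bonds
  b2 <- build_connectivity(nap)$bonds
  expect_identical(b1, b2)
  expect_true(all(b1[, 1L] < b1[, 2L]))
})
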