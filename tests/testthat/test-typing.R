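test_that("type graphs compile with the expected shape", {
  b <- fixture_bank("minimal6")
  tg <- compile_type(b$entries[[3L]])    # methyl carbon
  expect_length(tg$labels, 5L)
  expect_equal(tg$depth, 1L)
  expect_equal(igraph::ecount(tg$graph), 4L)   # star
  tg_h <- compile_type(b$entries[[2L]])  # aromatic hydrogen
  expect_equal(tg_h$depth, 2L)
  # ring relations ride along as post-match constraints, not edges
  tg_c <- compile_type(b$entries[[1L]])
  expect_length(tg_c$ring_relations, 1L)
  expect_equal(igraph::ecount(tg_c$graph), 3L)
})

test_that("methyl type matches ethane but not methane", {
  b <- fixture_bank("minimal6")
  tg <- compile_type(b$entries[[3L]])
  met <- make_molecule("methane")
  eth <- make_molecule("ethane")
  expect_null(match_type(tg, 1L, met))
  m <- match_type(tg, 1L, eth)
  expect_false(is.null(m))
  expect_equal(unname(m["C1"]), 1L)
  expect_equal(unname(m["C2"]), 2L)
})

test_that("different-ring relations reject naphthalene bridgeheads", {
  nap <- make_molecule("naphthalene")
  d <- compute_descriptors(nap)
  bridge <- which(vapply(d, function(x) nrow(x$rings) == 2L, TRUE))[1L]
  mk <- function(relation) atom_type_definition(
    type_id = "T", central = "C0",
    rules = list(
      connectivity_rule("C0", "C", c("Ca", "Cb", "Cc")),
      connectivity_rule("Ca", "C", "C0", rings = "6a"),
      connectivity_rule("Cb", "C", "C0", rings = "6a"),
      connectivity_rule("Cc", "C", "C0")),
    ring_relations = list(list(relation = relation, a = "Ca", b = "Cb")),
    frame = frame_spec("Z", "Ca", "X", "Cb"), symmetry = "no")
  tg_same <- compile_type(mk("same_ring"))
  tg_diff <- compile_type(mk("different_ring"))
  expect_false(is.null(match_type(tg_same, bridge, nap)))
  # every neighbor pair of a bridgehead shares a ring with it adjacent:
  # two ring neighbors always share one ring -> different_ring must fail
  # only if no assignment keeps them apart; the bridgehead's three ring
  # neighbors span the two rings, so a valid different-ring pair exists
  expect_false(is.null(match_type(tg_diff, bridge, nap)))
  # an ordinary aromatic carbon has all ring neighbors in its single ring
  plain <- which(vapply(seq_along(d), function(i)
    nap$z[i] == 6L && nrow(d[[i]]$rings) == 1L &&
      d[[i]]$n_neighbors == 3L, TRUE))
  # pick one whose three neighbors include two ring carbons only
  ch <- plain[vapply(plain, function(i) {
    nb <- which(nap$bonds[, 1L] == i | nap$bonds[, 2L] == i)
    sum(nap$z[setdiff(as.integer(nap$bonds[nb, ]), i)] == 6L) == 2L
  }, TRUE)][1L]
  expect_null(match_type(tg_diff, ch, nap))
})

test_that("assignment takes the first matching entry in bank order", {
  eth <- make_molecule("ethane")
  good <- fixture_bank("ordering")       # detailed first
  bad <- fixture_bank("ordering_bad")    # general first
  a1 <- assign_types(eth, good)
  a2 <- assign_types(eth, bad)
  expect_equal(a1$type_id[1L], "Cme")
  expect_equal(a2$type_id[1L], "Cgen4")  # shadowed by the general entry
  # empty bank assigns nothing
  a0 <- assign_types(eth, bank(list()))
  expect_true(all(is.na(a0$type_id)))
})

test_that("the fixture bank types benzene and water completely", {
  b <- fixture_bank("minimal6")
  ab <- assign_types(make_molecule("benzene"), b)
  expect_equal(sum(ab$type_id == "Car", na.rm = TRUE), 6L)
  expect_equal(sum(ab$type_id == "Har", na.rm = TRUE), 6L)
  aw <- assign_types(make_molecule("water"), b)
  expect_identical(aw$type_id, c("Ow", "Hw", "Hw"))
})

test_that("matching agrees with brute-force enumeration on random colored graphs", {
  set.seed(2024)
  n_cases <- 220L
  n_matches <- 0L
  stub <- make_molecule("water")   # placeholder; matching uses descriptors
  for (case in seq_len(n_cases)) {
    g <- random_colored_graph(8L)
    atom <- sample(g$n, 1L)
    entry <- if (case %% 2L == 0L) pattern_from_target(g, atom)
             else random_pattern_entry(3L)
    tg <- compile_type(entry)
    got <- !is.null(match_type(tg, atom, stub, descriptors = g$descriptors,
                               target_graph = g$graph))
    want <- brute_force_match(entry, atom, g$adj, g$descriptors)
    expect_identical(got, want,
                     label = paste("case", case, "atom", atom))
    if (want) n_matches <- n_matches + 1L
  }
  # the case set must exercise both outcomes to be meaningful
  expect_gt(n_matches, 10L)
  expect_lt(n_matches, n_cases - 10L)
})

test_that("assignments are invariant under atom permutation", {
  b <- fixture_bank("minimal6")
  s <- make_molecule("benzene", connect = FALSE)
  a_ref <- assign_types(perceive_rings(build_connectivity(s)), b)
  ref <- stats::setNames(a_ref$type_id, s$labels[a_ref$atom])
  set.seed(9)
  for (rep in 1:3) {
    p <- sample(length(s$z))
    s2 <- molecular_structure(s$z[p], s$xyz[p, ], labels = s$labels[p])
    a2 <- assign_types(perceive_rings(build_connectivity(s2)), b)
    got <- stats::setNames(a2$type_id, s2$labels[a2$atom])
    expect_identical(got[names(ref)], ref)
  }
})

test_that("appending entries never changes existing assignments", {
  b <- fixture_bank("minimal6")
  eth <- make_molecule("ethane")
  a1 <- assign_types(eth, b)
  b_app <- bank(c(b$entries, list(taamkit:::.entry_generic_C4())))
  a2 <- assign_types(eth, b_app)
  expect_identical(a2$type_id, a1$type_id)
  # prepending can only switch atoms to the new entry
  b_pre <- bank(c(list(taamkit:::.entry_generic_C4()), b$entries))
  a3 <- assign_types(eth, b_pre)
  changed <- which(a3$type_id != a1$type_id)
  expect_true(all(a3$type_id[changed] == "Cgen4"))
})

test_that("unassigned atoms group by topology, sorted by group size", {
  b <- fixture_bank("minimal6")
  # methane (5 unassigned), perchlorate (5 unassigned in 2 groups),
  # pf6 (7 unassigned in 2 groups)
  structures <- list(make_molecule("methane"), make_molecule("perchlorate"))
  cs <- coverage_stats(structures, b)
  g <- cs$groups
  expect_equal(sum(g$count), 10L)
  expect_true(all(diff(g$count) <= 0))           # descending
  expect_equal(g$count[1L], 4L)                  # methane hydrogens
  # all-assigned set gives the empty grouping
  cs2 <- coverage_stats(list(make_molecule("water")), b)
  expect_equal(nrow(cs2$groups), 0L)
  # constructed 5/3/1 group sizes come out in that order
  s1 <- make_molecule("pf6")        # 6 F + 1 P unassigned: groups 6 and 1
  cs3 <- coverage_stats(list(s1), b)
  expect_identical(cs3$groups$count, c(6L, 1L))
})

test_that("coverage fractions follow the definitions exactly", {
  b <- fixture_bank("minimal6")
  benz <- make_molecule("benzene")      # 12/12 assigned
  met <- make_molecule("methane")       # 0/5 assigned
  cs <- coverage_stats(list(benz, met), b)
  expect_equal(cs$atom_fraction, 100 * 12 / 17)
  expect_equal(cs$structure_fraction, 50)
  expect_equal(cs$n_full, 1L)
  cs2 <- coverage_stats(list(benz, make_molecule("water")), b)
  expect_equal(cs2$structure_fraction, 100)
  expect_error(coverage_stats(list(), b), "empty")
  # weighted-mean identity: overall atom fraction equals the atom-weighted
  # mean of per-structure fractions
  f_benz <- 100 * 12 / 12; f_met <- 0
  expect_equal(cs$atom_fraction, (12 * f_benz + 5 * f_met) / 17)
})
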