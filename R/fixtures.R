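# Built-in synthetic structures, banks and instance-parameter sets.  Every
# fixture is generated from embedded constants (and an explicit seed where
# randomness is involved), so the whole package is testable offline.

.deg <- pi / 180

.tetrahedral_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                           c(-1, -1, 1)) / sqrt(3)

.make_methane <- function() {
  molecular_structure(c("C", rep("H", 4)),
                      rbind(c(0, 0, 0), 1.089 * .tetrahedral_dirs))
}

.make_ethane <- function() {
  # staggered, C-C along z
  cc <- 1.526; ch <- 1.089; ang <- 111.2 * .deg
  zc <- cc / 2
  h <- function(zsign, phi0) t(vapply(0:2, function(k) {
    phi <- phi0 + k * 2 * pi / 3
    c(ch * sin(pi - ang) * cos(phi), ch * sin(pi - ang) * sin(phi),
      zsign * (zc + ch * cos(pi - ang) * -1))
  }, numeric(3)))
  # hydrogens tilt away from the opposite carbon
  h1 <- t(vapply(0:2, function(k) {
    phi <- k * 2 * pi / 3
    c(ch * sin(ang) * cos(phi), ch * sin(ang) * sin(phi),
      zc + ch * cos(ang))
  }, numeric(3)))
  h2 <- t(vapply(0:2, function(k) {
    phi <- pi / 3 + k * 2 * pi / 3
    c(ch * sin(ang) * cos(phi), ch * sin(ang) * sin(phi),
      -zc - ch * cos(ang))
  }, numeric(3)))
  molecular_structure(c("C", "C", rep("H", 6)),
                      rbind(c(0, 0, zc), c(0, 0, -zc), h1, h2))
}

.make_water <- function() {
  # O at origin, H in the xz plane, bisector along +z
  r <- 0.9572; half <- 104.52 / 2 * .deg
  molecular_structure(c("O", "H", "H"),
                      rbind(c(0, 0, 0),
                            c(r * sin(half), 0, r * cos(half)),
                            c(-r * sin(half), 0, r * cos(half))))
}

.make_hydronium <- function() {
  # trigonal pyramid, 3-fold axis along z
  r <- 0.980; hoh <- 111.3 * .deg
  # polar angle theta from the axis such that the H-O-H angle is hoh
  # from cos(hoh) = 1 - 1.5 sin^2(theta)
  theta <- acos(sqrt(1 - (1 - cos(hoh)) / 1.5))
  h <- t(vapply(0:2, function(k) {
    phi <- k * 2 * pi / 3
    r * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }, numeric(3)))
  molecular_structure(c("O", "H", "H", "H"), rbind(c(0, 0, 0), h))
}

.make_benzene <- function() {
  rc <- 1.39; rh <- 1.39 + 1.083
  phi <- (0:5) * pi / 3
  xyz <- rbind(cbind(rc * cos(phi), rc * sin(phi), 0),
               cbind(rh * cos(phi), rh * sin(phi), 0))
  molecular_structure(c(rep("C", 6), rep("H", 6)), xyz)
}

.make_naphthalene <- function() {
  # two regular hexagons (bond 1.40) sharing an edge, H on the 8 CH carbons
  a <- 1.40
  hexagon <- function(cx) cbind(cx + a * cos((0:5) * pi / 3 + pi / 6),
                                a * sin((0:5) * pi / 3 + pi / 6), 0)
  c1 <- hexagon(-a * sqrt(3) / 2)
  c2 <- hexagon(a * sqrt(3) / 2)
  pts <- rbind(c1, c2)
  key <- apply(round(pts, 6), 1L, paste, collapse = ",")
  pts <- pts[!duplicated(key), , drop = FALSE]
  # hydrogens: carbons with only two carbon neighbors get an outward H
  d <- as.matrix(stats::dist(pts))
  hxyz <- NULL
  for (i in seq_len(nrow(pts))) {
    nb <- which(d[i, ] > 0 & d[i, ] < 1.6)
    if (length(nb) == 2L) {
      dir <- pts[i, ] - colMeans(pts[nb, , drop = FALSE])
      dir <- dir / sqrt(sum(dir^2))
      hxyz <- rbind(hxyz, pts[i, ] + 1.083 * dir)
    }
  }
  molecular_structure(c(rep("C", nrow(pts)), rep("H", nrow(hxyz))),
                      rbind(pts, hxyz))
}

.make_cyclopropane <- function() {
  side <- 1.510; rc <- side / sqrt(3); ch <- 1.089
  beta <- 57.7 * .deg   # H elevation from the ring plane
  xyz <- NULL; sym <- character(0)
  for (k in 0:2) {
    phi <- k * 2 * pi / 3
    cpos <- c(rc * cos(phi), rc * sin(phi), 0)
    out <- c(cos(phi), sin(phi), 0)
    xyz <- rbind(xyz, cpos,
                 cpos + ch * (cos(beta) * out + sin(beta) * c(0, 0, 1)),
                 cpos + ch * (cos(beta) * out - sin(beta) * c(0, 0, 1)))
    sym <- c(sym, "C", "H", "H")
  }
  molecular_structure(sym, xyz)
}

.make_nitromethane <- function() {
  cn <- 1.489; no <- 1.224; ono <- 125.3 * .deg; ch <- 1.089
  ang <- 109 * .deg
  n <- c(0, 0, 0); cpos <- c(0, 0, -cn)
  o <- rbind(c(no * sin(ono / 2), 0, no * cos(ono / 2)),
             c(-no * sin(ono / 2), 0, no * cos(ono / 2)))
  h <- t(vapply(0:2, function(k) {
    phi <- pi / 2 + k * 2 * pi / 3
    cpos + ch * c(sin(ang) * cos(phi), sin(ang) * sin(phi), -cos(pi - ang))
  }, numeric(3)))
  molecular_structure(c("N", "C", "O", "O", "H", "H", "H"),
                      rbind(n, cpos, o, h))
}

.make_perchlorate <- function() {
  molecular_structure(c("Cl", rep("O", 4)),
                      rbind(c(0, 0, 0), 1.44 * .tetrahedral_dirs))
}

.make_pf6 <- function() {
  dirs <- rbind(diag(3), -diag(3))
  molecular_structure(c("P", rep("F", 6)), rbind(c(0, 0, 0), 1.60 * dirs))
}

.make_p1_chain <- function() {
  # toy P1 crystal: cumulated =C(H2)= chain running along a, so covalent
  # bonds cross the cell boundary and cluster growth must expand images
  cell <- c(1.335, 10, 10, 90, 90, 90)
  M <- frac_to_cart_matrix(cell)
  frac <- rbind(c(0, 0, 0), c(0, 0.093, 0), c(0, -0.093, 0))
  molecular_structure(c("C", "H", "H"), frac %*% t(M), cell = cell,
                      labels = c("C1", "H1", "H2"))
}

#' Synthetic molecule catalog
#'
#' Idealized geometries from embedded constants; deterministic.
#'
#' @param name One of `"methane"`, `"ethane"`, `"water"`, `"hydronium"`,
#'   `"benzene"`, `"naphthalene"`, `"cyclopropane"`, `"nitromethane"`,
#'   `"perchlorate"`, `"pf6"`, `"p1_chain"`.
#' @param connect Build covalent connectivity before returning.
#' @return A `molecular_structure`.
#' @export
make_molecule <- function(name, connect = TRUE) {
  maker <- switch(name,
    methane = .make_methane, ethane = .make_ethane, water = .make_water,
    hydronium = .make_hydronium, benzene = .make_benzene,
    naphthalene = .make_naphthalene, cyclopropane = .make_cyclopropane,
    nitromethane = .make_nitromethane, perchlorate = .make_perchlorate,
    pf6 = .make_pf6, p1_chain = .make_p1_chain,
    stop("unknown fixture molecule: '", name, "'"))
  s <- maker()
  if (connect) s <- perceive_rings(build_connectivity(s))
  s
}

#' Names of the catalog molecules
#' @return Character vector.
#' @export
fixture_molecules <- function() {
  c("methane", "ethane", "water", "hydronium", "benzene", "naphthalene",
    "cyclopropane", "nitromethane", "perchlorate", "pf6", "p1_chain")
}

# --- fixture banks ---------------------------------------------------------

.entry_params <- function(p_val, kappa, kappa_prime, plm_list, l_max = 4L,
                          ssd = 0, n = 5L) {
  pm <- plm_zero(l_max)
  for (nm in names(plm_list)) {
    lm <- as.integer(strsplit(nm, ",")[[1L]])
    pm <- plm_set(pm, lm[1L], lm[2L], plm_list[[nm]])
  }
  ps <- plm_zero(l_max); pn <- plm_zero(l_max)
  pn[pm != 0] <- n
  ps[pm != 0] <- ssd
  list(p_val = c(p_val, ssd, n), kappa = c(kappa, ssd / 10, n),
       kappa_prime = c(kappa_prime, ssd, n),
       plm_mean = pm, plm_ssd = ps, plm_n = pn, l_max = l_max)
}

.entry_aromatic_C <- function() {
  atom_type_definition(
    type_id = "Car", central = "C1",
    rules = list(
      connectivity_rule("C1", "C", c("C2", "C3", "H1"), planar = "yes",
                        rings = "6p"),
      connectivity_rule("C2", "C", "C1", rings = "6p"),
      connectivity_rule("C3", "C", "C1", rings = "6p"),
      connectivity_rule("H1", "H", "C1")),
    ring_relations = list(list(relation = "same_ring", a = "C2", b = "C3")),
    frame = frame_spec("Z", "C2", "X", "C3"), symmetry = "m",
    params = .entry_params(4.01, 0.99, 0.92,
                           list("1,1" = 0.03, "2,0" = -0.20, "2,2" = 0.06,
                                "3,3" = 0.25)),
    comment = "aromatic CH carbon in a planar six-ring")
}

.entry_aromatic_H <- function() {
  atom_type_definition(
    type_id = "Har", central = "H1",
    rules = list(
      connectivity_rule("H1", "H", "C1"),
      connectivity_rule("C1", "C", c("H1", "C2", "C3"), planar = "yes",
                        rings = "6p"),
      connectivity_rule("C2", "C", "C1"),
      connectivity_rule("C3", "C", "C1")),
    frame = frame_spec("Z", "C1", "X", "C2"), symmetry = "cyl",
    params = .entry_params(0.83, 1.16, 1.19,
                           list("1,0" = 0.15, "2,0" = 0.05), l_max = 2L),
    comment = "hydrogen on an aromatic carbon")
}

.entry_methyl_C <- function() {
  atom_type_definition(
    type_id = "Cme", central = "C1",
    rules = list(
      connectivity_rule("C1", "C", c("H1", "H2", "H3", "C2")),
      connectivity_rule("H1", "H", "C1"),
      connectivity_rule("H2", "H", "C1"),
      connectivity_rule("H3", "H", "C1"),
      connectivity_rule("C2", "C", "C1")),
    frame = frame_spec("Z", "C2", "X", "H1"), symmetry = "3m",
    params = .entry_params(4.06, 1.00, 0.90,
                           list("1,0" = -0.06, "2,0" = 0.08, "3,0" = 0.02,
                                "3,3" = 0.18)),
    comment = "methyl carbon bonded to carbon")
}

.entry_methyl_H <- function() {
  atom_type_definition(
    type_id = "Hme", central = "H1",
    rules = list(
      connectivity_rule("H1", "H", "C1"),
      connectivity_rule("C1", "C", c("H1", "H2", "H3", "C2")),
      connectivity_rule("H2", "H", "C1"),
      connectivity_rule("H3", "H", "C1"),
      connectivity_rule("C2", "C", "C1")),
    frame = frame_spec("Z", "C1", "X", "C2"), symmetry = "cyl",
    params = .entry_params(0.92, 1.12, 1.18,
                           list("1,0" = 0.13, "2,0" = 0.06), l_max = 2L),
    comment = "methyl hydrogen")
}

.entry_water_O <- function() {
  atom_type_definition(
    type_id = "Ow", central = "O1",
    rules = list(
      connectivity_rule("O1", "O", c("H1", "H2")),
      connectivity_rule("H1", "H", "O1"),
      connectivity_rule("H2", "H", "O1")),
    frame = frame_spec("Z", c("H1", "H2"), "X", "H1"), symmetry = "mm2",
    params = .entry_params(6.24, 0.97, 0.93,
                           list("1,0" = 0.12, "2,0" = -0.05, "2,2" = 0.09,
                                "3,0" = 0.02)),
    comment = "water oxygen")
}

.entry_water_H <- function() {
  atom_type_definition(
    type_id = "Hw", central = "H1",
    rules = list(
      connectivity_rule("H1", "H", "O1"),
      connectivity_rule("O1", "O", c("H1", "H2")),
      connectivity_rule("H2", "H", "O1")),
    frame = frame_spec("Z", "O1", "X", "H2"), symmetry = "cyl",
    params = .entry_params(0.70, 1.18, 1.20,
                           list("1,0" = 0.14, "2,0" = 0.07), l_max = 2L),
    comment = "water hydrogen")
}

.entry_generic_C4 <- function() {
  atom_type_definition(
    type_id = "Cgen4", central = "C1",
    rules = list(
      connectivity_rule("C1", "C", c("X1", "X2", "X3", "X4")),
      connectivity_rule("X1", "X", "C1"),
      connectivity_rule("X2", "X", "C1"),
      connectivity_rule("X3", "X", "C1"),
      connectivity_rule("X4", "X", "C1")),
    frame = frame_spec("Z", "X1", "X", "X2"), symmetry = "no",
    params = .entry_params(4.00, 1.00, 1.00, list()),
    comment = "generic four-coordinated carbon")
}

#' Fixture banks
#'
#' `"minimal6"`: aromatic C/H, methyl C/H and water O/H types with
#' plausible parameter values.  `"ordering"`: methyl carbon followed by a
#' generic four-coordinated carbon (the sound order);
#' `"ordering_bad"`: the same two entries reversed, which
#' [check_entry_order()] flags.
#'
#' @param name `"minimal6"`, `"ordering"` or `"ordering_bad"`.
#' @return A `bank` object.
#' @export
fixture_bank <- function(name = "minimal6") {
  switch(name,
    minimal6 = bank(list(.entry_aromatic_C(), .entry_aromatic_H(),
                         .entry_methyl_C(), .entry_methyl_H(),
                         .entry_water_O(), .entry_water_H())),
    ordering = bank(list(.entry_methyl_C(), .entry_generic_C4())),
    ordering_bad = bank(list(.entry_generic_C4(), .entry_methyl_C())),
    stop("unknown fixture bank: '", name, "'"))
}

# --- noisy instance sets ---------------------------------------------------

# Deterministic random proper rotation from 3 normal deviates.
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) { q <- q / n; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Draw noisy parameter instances around a bank entry
#'
#' Emulates per-atom refinement results for averaging tests: parameter
#' values are drawn around the entry means with the given Gaussian sigmas,
#' and each instance is expressed in a random proper rotation of the type
#' frame (its populations rotated accordingly).
#'
#' @param entry An `atom_type_definition`.
#' @param n Number of instances.
#' @param sigma Named list of sigmas: `p_val`, `kappa`, `kappa_prime`,
#'   `plm` (one sigma shared by all populations); missing names mean 0.
#' @param seed Integer seed (all randomness is funneled through it).
#' @return List of `parameter_instance` objects: `source`, `params`
#'   (a [multipole_parameters()]), `frame` (the instance's local frame) and
#'   `type_id`.
#' @export
make_noisy_instances <- function(entry, n, sigma = list(), seed = 0L) {
  s <- function(nm) sigma[[nm]] %||% 0
  set.seed(seed)
  p <- entry$params
  out <- vector("list", n)
  for (i in seq_len(n)) {
    R <- .random_rotation()
    plm <- p$plm_mean
    idx <- plm_indices(p$l_max)
    for (k in seq_len(nrow(idx))) {
      v <- plm_get(plm, idx[k, "l"], idx[k, "m"])
      if (v != 0 || s("plm") > 0)
        plm <- plm_set(plm, idx[k, "l"], idx[k, "m"],
                       v + stats::rnorm(1, 0, s("plm")))
    }
    # express populations in the instance's own (rotated) frame: the
    # instance frame differs from the type frame by R
    plm_inst <- rotate_plm(plm, t(R))
    attr(plm_inst, "l_max") <- p$l_max
    params <- multipole_parameters(
      p_val = p$p_val[1L] + stats::rnorm(1, 0, s("p_val")),
      kappa = max(0.05, p$kappa[1L] + stats::rnorm(1, 0, s("kappa"))),
      kappa_prime = max(0.05, p$kappa_prime[1L] +
                          stats::rnorm(1, 0, s("kappa_prime"))),
      plm = plm_inst, l_max = p$l_max)
    out[[i]] <- structure(list(source = sprintf("synthetic:%s:%d",
                                                entry$type_id, i),
                               params = params,
                               frame = local_frame(rotation = R),
                               type_id = entry$type_id),
                          class = "parameter_instance")
  }
  out
}
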