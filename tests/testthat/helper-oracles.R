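# Shared helpers: independent oracles (brute-force matching, quadrature)
# and fixture builders used across test files.

# --- numeric quadrature on the sphere / radial axis ------------------------

# integral of f(z, phi) over the sphere via a fine product grid
sphere_integral <- function(f, n_theta = 400L, n_phi = 400L) {
  z <- seq(-1 + 1 / n_theta, 1 - 1 / n_theta, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-1L]
  g <- expand.grid(z = z, phi = phi)
  mean(f(g$z, g$phi)) * 4 * pi
}

# spherical Bessel j_l via half-integer Bessel J (independent of the
# package's trig/series implementation)
sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-8
  out[small] <- if (l == 0L) 1 else 0
  xb <- x[!small]
  out[!small] <- besselJ(xb, l + 0.5) * sqrt(pi / (2 * xb))
  out
}

# --- random colored graphs and a brute-force matcher -----------------------

# Random "structure side" colored graph: adjacency list + descriptor list.
random_colored_graph <- function(n_max = 8L) {
  n <- sample(3:n_max, 1L)
  edges <- NULL
  # random spanning tree + extra edges
  for (v in 2:n) edges <- rbind(edges, c(sample(v - 1L, 1L), v))
  extra <- sample(0:2, 1L)
  for (k in seq_len(extra)) {
    e <- sort(sample(n, 2L))
    edges <- rbind(edges, e)
  }
  edges <- unique(edges)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1L]]] <- c(adj[[edges[i, 1L]]], edges[i, 2L])
    adj[[edges[i, 2L]]] <- c(adj[[edges[i, 2L]]], edges[i, 1L])
  }
  descriptors <- lapply(seq_len(n), function(i) {
    nr <- sample(0:2, 1L, prob = c(0.6, 0.3, 0.1))
    rings <- if (nr > 0)
      cbind(size = sample(3:7, nr, replace = TRUE),
            planar = sample(0:1, nr, replace = TRUE))
    else matrix(integer(0), 0L, 2L,
                dimnames = list(NULL, c("size", "planar")))
    list(z = sample(c(6L, 6L, 7L, 8L, 1L), 1L),
         n_neighbors = length(adj[[i]]),
         planar = sample(c(TRUE, FALSE, NA), 1L),
         rings = rings, ring_ids = integer(0))
  })
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = n,
                          directed = FALSE)
  list(n = n, edges = edges, adj = adj, descriptors = descriptors,
       graph = g)
}

# Random pattern entry: a small tree of colored rules rooted at "A1".
random_pattern_entry <- function(max_extra = 3L) {
  n <- 2L + sample(0:max_extra, 1L)
  labs <- paste0("A", seq_len(n))
  parent <- c(NA, vapply(2:n, function(v) sample(v - 1L, 1L), 0L))
  rules <- lapply(seq_len(n), function(v) {
    kids <- which(parent == v)
    bonded <- c(if (v > 1L) labs[parent[v]], labs[kids])
    elems <- if (stats::runif(1) < 0.35) "X"
             else sample(c("C", "C", "N", "O", "H"),
                         sample(1:2, 1L))
    nr <- stats::runif(1)
    rings <- if (nr < 0.85) "any"
             else if (nr < 0.92) "none"
             else paste0(sample(3:7, 1L), sample(c("p", "n", "a"), 1L))
    connectivity_rule(labs[v], unique(elems), bonded,
                      planar = sample(c("yes", "no", "any"), 1L,
                                      prob = c(0.1, 0.1, 0.8)),
                      rings = rings,
                      nb = if (stats::runif(1) < 0.08)
                        sample(1:4, 1L) else NA)
  })
  atom_type_definition(
    type_id = paste0("T", sample(1e6, 1L)), central = "A1", rules = rules,
    frame = frame_spec("Z", labs[2L], "X", labs[1L]), symmetry = "no")
}

# Pattern extracted from an actual neighborhood of the target graph, with
# colors copied from the descriptors and occasionally loosened or mutated;
# yields a healthy share of positive cases.
pattern_from_target <- function(g, atom) {
  nb <- g$adj[[atom]]
  take <- nb[stats::runif(length(nb)) < 0.9]
  if (!length(take)) take <- nb[1L]
  verts <- c(atom, take)
  labs <- paste0("A", seq_along(verts))
  rules <- lapply(seq_along(verts), function(k) {
    v <- verts[k]
    d <- g$descriptors[[v]]
    bonded <- if (k == 1L) labs[-1L] else labs[1L]
    elems <- if (stats::runif(1) < 0.3) "X"
             else if (stats::runif(1) < 0.15)  # mutate: likely mismatch
               sample(c("H", "C", "N", "O"), 1L)
             else element_symbol(d$z)
    planar <- if (stats::runif(1) < 0.6) "any"
              else if (isTRUE(d$planar)) "yes"
              else if (isFALSE(d$planar)) "no" else "any"
    rings <- if (stats::runif(1) < 0.8) "any"
             else if (nrow(d$rings) == 0L) "none"
             else paste0(d$rings[1L, "size"],
                         if (d$rings[1L, "planar"] == 1) "p" else "n")
    connectivity_rule(labs[k], elems, bonded, planar = planar,
                      rings = rings,
                      nb = if (k > 1L && stats::runif(1) < 0.15)
                        d$n_neighbors else NA)
  })
  atom_type_definition(
    type_id = paste0("E", sample(1e6, 1L)), central = "A1", rules = rules,
    frame = frame_spec("Z", labs[2L], "X", labs[1L]), symmetry = "no")
}

# Independent color compatibility check (deliberately re-derived, not the
# package's .color_match).
oracle_color_ok <- function(rule, d) {
  if (!is.null(rule$elements) && !(d$z %in% rule$elements)) return(FALSE)
  if (!is.na(rule$nb) && rule$nb != d$n_neighbors) return(FALSE)
  if (rule$planar == "yes" && !identical(d$planar, TRUE)) return(FALSE)
  if (rule$planar == "no" && !identical(d$planar, FALSE)) return(FALSE)
  if (identical(rule$rings, "none") && nrow(d$rings) > 0L) return(FALSE)
  if (!identical(rule$rings, "any") && !identical(rule$rings, "none")) {
    for (i in seq_len(nrow(rule$rings))) {
      sz <- as.integer(rule$rings[i, "size"])
      pl <- rule$rings[i, "planar"]
      ok <- FALSE
      for (j in seq_len(nrow(d$rings))) {
        if (d$rings[j, "size"] != sz) next
        if (pl == "a" || (pl == "p" && d$rings[j, "planar"] == 1) ||
            (pl == "n" && d$rings[j, "planar"] == 0)) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

# Exhaustive enumeration of injective root-anchored mappings.
brute_force_match <- function(entry, atom, adj, descriptors) {
  rules <- entry$rules
  labs <- names(rules)
  # effective central neighbor-count constraint, as documented
  ce <- rules[[entry$central]]
  if (is.na(ce$nb)) rules[[entry$central]]$nb <- length(ce$bonded_to)
  ord <- entry$central
  while (length(ord) < length(labs)) {
    nxt <- setdiff(unique(unlist(lapply(rules[ord], `[[`, "bonded_to"))),
                   ord)
    if (!length(nxt)) nxt <- setdiff(labs, ord)[1L]
    ord <- c(ord, nxt)
  }
  n_target <- length(descriptors)
  rec <- function(map) {
    k <- length(map) + 1L
    if (k > length(ord)) return(TRUE)
    v <- ord[k]
    cands <- if (v == entry$central) atom else seq_len(n_target)
    for (w in setdiff(cands, unlist(map))) {
      if (!oracle_color_ok(rules[[v]], descriptors[[w]])) next
      ok <- TRUE
      for (u in intersect(rules[[v]]$bonded_to, names(map)))
        if (!(map[[u]] %in% adj[[w]])) { ok <- FALSE; break }
      # also check edges declared on already-mapped vertices toward v
      if (ok) for (u in names(map))
        if (v %in% rules[[u]]$bonded_to && !(map[[u]] %in% adj[[w]])) {
          ok <- FALSE; break
        }
      if (!ok) next
      map2 <- map; map2[[v]] <- w
      if (rec(map2)) return(TRUE)
    }
    FALSE
  }
  rec(stats::setNames(list(), character(0)))
}

# --- water scattering fixture ----------------------------------------------

make_plm <- function(values, l_max = 4L) {
  p <- plm_zero(l_max)
  for (nm in names(values)) {
    lm <- as.integer(strsplit(nm, ",")[[1L]])
    p <- plm_set(p, lm[1L], lm[2L], values[[nm]])
  }
  p
}

# Water pseudoatom model; `perturbed` selects the target parameter set,
# otherwise the neutral spherical start.
water_model <- function(a = 30, perturbed = TRUE, kappa_prime = FALSE) {
  w <- make_molecule("water")
  w$xyz <- sweep(w$xyz, 2L, rep(-a / 2, 3L), "-")
  mp <- function(pv, k, kp, vals, lm = 4L)
    multipole_parameters(pv, k, kp, make_plm(vals, lm), l_max = lm)
  frO <- build_frame(w, 1L, frame_spec("Z", c("H1", "H2"), "X", "H1"),
                     c(H1 = 2L, H2 = 3L))
  frH1 <- build_frame(w, 2L, frame_spec("Z", "O1", "X", "H2"),
                      c(O1 = 1L, H2 = 3L))
  frH2 <- build_frame(w, 3L, frame_spec("Z", "O1", "X", "H1"),
                      c(O1 = 1L, H1 = 2L))
  kp <- if (kappa_prime) c(0.93, 1.2) else c(1, 1)
  sites <- if (perturbed) list(
    list(params = mp(6.30, 0.97, kp[1L],
                     list("1,0" = 0.12, "2,0" = -0.05, "2,2" = 0.09)),
         frame = frO, symmetry = "mm2"),
    list(params = mp(0.85, 1.15, kp[2L],
                     list("1,0" = 0.14, "2,0" = 0.06), lm = 2L),
         frame = frH1, symmetry = "cyl"),
    list(params = mp(0.85, 1.15, kp[2L],
                     list("1,0" = 0.14, "2,0" = 0.06), lm = 2L),
         frame = frH2, symmetry = "cyl"))
  else list(
    list(params = mp(6, 1, 1, list()), frame = frO, symmetry = "mm2"),
    list(params = mp(1, 1, 1, list(), lm = 2L), frame = frH1,
         symmetry = "cyl"),
    list(params = mp(1, 1, 1, list(), lm = 2L), frame = frH2,
         symmetry = "cyl"))
  pseudoatom_model(w, a = a, sites = sites,
                   kappa_groups = c(1L, 2L, 2L))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

random_plm <- function(l_max = 4L) {
  p <- plm_zero(l_max)
  idx <- plm_indices(l_max)
  for (i in seq_len(nrow(idx)))
    p <- plm_set(p, idx[i, "l"], idx[i, "m"], stats::rnorm(1, 0, 0.2))
  p
}

# density of a pure deformation population table at unit radius directions
plm_density <- function(plm, u, l_max = 4L) {
  out <- numeric(nrow(u))
  for (l in 0:l_max) for (m in seq.int(-l, l)) {
    p <- plm_get(plm, l, m)
    if (p != 0) out <- out + p * real_spherical_harmonic(l, m, u)
  }
  out
}

random_directions <- function(n) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3L)
  u / sqrt(rowSums(u^2))
}
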