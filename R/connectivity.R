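# Covalent connectivity, ring perception (SSSR), planarity descriptors,
# cluster growth for periodic structures and X-H bond re-normalization.

.read_keyval <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  parts <- strsplit(lines, "\\s+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
                  vapply(parts, `[[`, "", 1L))
}

#' Covalent radii table
#'
#' @param path Optional key-value text file (`element radius`); defaults to
#'   the table shipped with the package.
#' @return Named numeric vector of radii in Angstrom.
#' @export
covalent_radii <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "covalent_radii.txt", package = "taamkit",
                        mustWork = TRUE)
  .read_keyval(path)
}

#' Neutron X-H distance table
#'
#' @param path Optional key-value text file; keys are `element` or
#'   `element.coordination`, values are distances in Angstrom.
#' @return Named numeric vector.
#' @export
neutron_xh_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "neutron_xh.txt", package = "taamkit",
                        mustWork = TRUE)
  .read_keyval(path)
}

#' Build covalent connectivity
#'
#' Atoms are bonded when their distance does not exceed the sum of covalent
#' radii plus a fixed slack (0.4 Angstrom).  A hydrogen atom acquiring two
#' or more bonds this way (short hydrogen bonds read as covalent) keeps
#' only its shortest bond; such atoms are reported in the
#' `multivalent_hydrogens` attribute of the bond matrix.
#'
#' @param structure A `molecular_structure`.
#' @param radii Named radii vector from [covalent_radii()].
#' @param slack Bond-detection slack in Angstrom.
#' @return The structure with `$bonds` set (2-column index matrix, i < j).
#' @export
build_connectivity <- function(structure, radii = covalent_radii(),
                               slack = 0.4) {
  sym <- element_symbol(structure$z)
  miss <- setdiff(unique(sym), names(radii))
  if (length(miss)) stop("no covalent radius for element(s): ",
                         paste(miss, collapse = ", "))
  r <- radii[sym]
  D <- as.matrix(stats::dist(structure$xyz))
  diag(D) <- Inf
  if (any(D < 0.3)) {
    idx <- which(D < 0.3, arr.ind = TRUE)[1L, ]
    stop("overlapping atoms ", structure$labels[idx[1L]], " / ",
         structure$labels[idx[2L]], " (distance < 0.3 Angstrom)")
  }
  cutoff <- outer(r, r, "+") + slack
  adj <- D <= cutoff
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  bonds <- cbind(pairs[, 1L], pairs[, 2L])
  # hydrogen shortest-bond policy
  flagged <- character(0)
  hyd <- which(structure$z == 1L)
  keep <- rep(TRUE, nrow(bonds))
  for (h in hyd) {
    at <- which(bonds[, 1L] == h | bonds[, 2L] == h)
    if (length(at) >= 2L) {
      flagged <- c(flagged, structure$labels[h])
      d <- D[cbind(bonds[at, 1L], bonds[at, 2L])]
      keep[at[-which.min(d)]] <- FALSE
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  attr(bonds, "multivalent_hydrogens") <- flagged
  structure$bonds <- bonds
  structure$rings <- NULL
  structure
}

.adjacency_list <- function(structure) {
  n <- length(structure$z)
  adj <- vector("list", n)
  b <- structure$bonds
  if (is.null(b)) stop("connectivity not built; call build_connectivity()")
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1L]]] <- c(adj[[b[i, 1L]]], b[i, 2L])
    adj[[b[i, 2L]]] <- c(adj[[b[i, 2L]]], b[i, 1L])
  }
  lapply(adj, sort)
}

# RMS deviation of points from their least-squares plane.
.plane_rms <- function(xyz) {
  if (nrow(xyz) < 4L) return(0)
  x <- sweep(xyz, 2L, colMeans(xyz))
  sv <- svd(x)
  sqrt(mean((x %*% sv$v[, 3L])^2))
}

# shortest path avoiding a given edge (BFS); returns vertex sequence or NULL
.bfs_path <- function(adj, from, to, skip_edge) {
  n <- length(adj)
  prev <- integer(n); seen <- logical(n)
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if ((v == skip_edge[1L] && w == skip_edge[2L]) ||
          (v == skip_edge[2L] && w == skip_edge[1L])) next
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == to) {
          path <- w
          while (path[1L] != from) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Perceive rings (smallest set of smallest rings)
#'
#' Finds a smallest set of smallest rings with sizes up to `max_size`,
#' breaking ties by lexicographic atom order, and annotates each ring with
#' its planarity (RMS deviation of the ring atoms from their least-squares
#' plane at most 0.1 Angstrom).
#'
#' @param structure A `molecular_structure` with connectivity.
#' @param max_size Largest ring size perceived (default 9).
#' @return The structure with `$rings` set: a list of
#'   `list(atoms, size, planar)`.
#' @export
perceive_rings <- function(structure, max_size = 9L) {
  adj <- .adjacency_list(structure)
  b <- structure$bonds
  n <- length(structure$z)
  structure$rings <- list()
  if (is.null(b) || nrow(b) == 0L) return(structure)
  g <- igraph::make_graph(edges = as.vector(t(b)), n = n, directed = FALSE)
  dim_cycle <- nrow(b) - n + igraph::components(g)$no
  if (dim_cycle <= 0L) return(structure)
  # candidate cycles: shortest cycle through each edge
  cand <- list()
  for (i in seq_len(nrow(b))) {
    p <- .bfs_path(adj, b[i, 1L], b[i, 2L], b[i, ])
    if (!is.null(p) && length(p) <= max_size) {
      cyc <- sort(p)
      key <- paste(cyc, collapse = ",")
      if (is.null(cand[[key]])) cand[[key]] <- p
    }
  }
  if (!length(cand)) return(structure)
  sizes <- vapply(cand, length, 0L)
  ord <- order(sizes, names(cand))
  # greedy GF(2)-independent selection on edge-incidence vectors
  edge_key <- paste(b[, 1L], b[, 2L], sep = "-")
  to_vec <- function(p) {
    k <- length(p)
    e1 <- p; e2 <- c(p[-1L], p[1L])
    keys <- paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
    v <- logical(nrow(b)); v[match(keys, edge_key)] <- TRUE
    v
  }
  basis <- NULL; chosen <- list()
  for (k in ord) {
    v <- to_vec(cand[[k]])
    red <- v
    if (!is.null(basis)) for (j in seq_len(ncol(basis))) {
      piv <- which(basis[, j])[1L]
      if (red[piv]) red <- xor(red, basis[, j])
    }
    if (any(red)) {
      basis <- cbind(basis, red)
      chosen[[length(chosen) + 1L]] <- cand[[k]]
      if (length(chosen) == dim_cycle) break
    }
  }
  structure$rings <- lapply(chosen, function(p)
    list(atoms = sort(p), size = length(p),
         planar = .plane_rms(structure$xyz[p, , drop = FALSE]) <= 0.1))
  structure
}

#' Atomic descriptors ("colors") for typing
#'
#' For each atom: atomic number, neighbor count, group planarity (defined
#' only for atoms with at least three neighbors: RMS deviation of the atom
#' and its neighbors from their least-squares plane at most 0.1 Angstrom)
#' and ring memberships `(size, ring planarity)`.
#'
#' @param structure A `molecular_structure` with connectivity (rings are
#'   perceived on the fly if absent).
#' @return A list with one descriptor set per atom: `z`, `n_neighbors`,
#'   `planar` (`TRUE`/`FALSE`/`NA`), `rings` (2-column matrix `size`,
#'   `planar`).
#' @export
compute_descriptors <- function(structure) {
  if (is.null(structure$rings)) structure <- perceive_rings(structure)
  adj <- .adjacency_list(structure)
  rings_of <- vector("list", length(structure$z))
  for (ri in seq_along(structure$rings)) {
    rg <- structure$rings[[ri]]
    for (a in rg$atoms) rings_of[[a]] <- c(rings_of[[a]], ri)
  }
  lapply(seq_along(structure$z), function(i) {
    nb <- adj[[i]]
    planar <- NA
    if (length(nb) >= 3L)
      planar <- .plane_rms(structure$xyz[c(i, nb), , drop = FALSE]) <= 0.1
    rg <- structure$rings[rings_of[[i]]]
    rmat <- if (length(rg))
      cbind(size = vapply(rg, `[[`, 0L, "size"),
            planar = vapply(rg, `[[`, TRUE, "planar"))
    else matrix(integer(0), 0L, 2L,
                dimnames = list(NULL, c("size", "planar")))
    list(z = structure$z[i], n_neighbors = length(nb), planar = planar,
         rings = rmat, ring_ids = rings_of[[i]])
  })
}

#' Grow a bonded cluster around the asymmetric unit
#'
#' For periodic structures the asymmetric-unit atoms are completed with
#' their bonded neighbors up to the `depth`-th shell, expanding across
#' translational images of the unit cell; isolated molecules are returned
#' unchanged.  Asymmetric-unit flags are preserved (image atoms are
#' flagged `FALSE`).
#'
#' @param structure A `molecular_structure` with connectivity; a `cell` is
#'   required for periodic expansion.
#' @param depth Number of bonded shells (>= 1).
#' @param radii,slack Passed to [build_connectivity()] for the expanded
#'   atom set.
#' @return A `molecular_structure` with connectivity built.
#' @export
grow_cluster <- function(structure, depth, radii = covalent_radii(),
                         slack = 0.4) {
  if (depth < 1L) stop("cluster depth must be >= 1")
  if (is.null(structure$cell)) {
    if (is.null(structure$bonds))
      structure <- build_connectivity(structure, radii, slack)
    return(structure)
  }
  cell <- structure$cell
  M <- frac_to_cart_matrix(cell)
  # bonded shells advance at most ~3 A per shell; expand images per axis
  span <- ceiling(depth * 3.0 / cell[1:3])
  shifts <- as.matrix(expand.grid(a = -span[1]:span[1],
                                  b = -span[2]:span[2],
                                  c = -span[3]:span[3]))
  n0 <- length(structure$z)
  big_xyz <- NULL; big_z <- integer(0); big_lab <- character(0)
  big_asu <- logical(0)
  for (s in seq_len(nrow(shifts))) {
    t_cart <- drop(M %*% as.numeric(shifts[s, ]))
    home <- all(shifts[s, ] == 0L)
    big_xyz <- rbind(big_xyz, sweep(structure$xyz, 2L, -t_cart))
    big_z <- c(big_z, structure$z)
    big_lab <- c(big_lab,
                 if (home) structure$labels
                 else paste0(structure$labels, "@",
                             paste(shifts[s, ], collapse = ",")))
    big_asu <- c(big_asu, if (home) structure$in_asu else rep(FALSE, n0))
  }
  big <- molecular_structure(big_z, big_xyz, labels = big_lab, cell = cell,
                             in_asu = big_asu)
  big <- build_connectivity(big, radii, slack)
  adj <- .adjacency_list(big)
  keep <- which(big_asu)
  frontier <- keep
  for (d in seq_len(depth)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), keep)
    if (!length(frontier)) break
    keep <- c(keep, frontier)
  }
  keep <- sort(keep)
  sub <- molecular_structure(big_z[keep], big_xyz[keep, , drop = FALSE],
                             labels = big_lab[keep], cell = cell,
                             in_asu = big_asu[keep])
  build_connectivity(sub, radii, slack)
}

#' Normalize X-H bond lengths to neutron distances
#'
#' Each hydrogen atom is moved along its existing bond vector so that the
#' X-H distance matches the tabulated averaged neutron value for the heavy
#' atom's chemical context; heavy atoms and bond directions are untouched.
#'
#' @param structure A `molecular_structure` with connectivity.
#' @param table Named distance vector from [neutron_xh_table()].
#' @return The structure with updated hydrogen coordinates.
#' @export
normalize_xh_bonds <- function(structure, table = neutron_xh_table()) {
  adj <- .adjacency_list(structure)
  sym <- element_symbol(structure$z)
  for (h in which(structure$z == 1L)) {
    nb <- adj[[h]]
    if (!length(nb)) {
      warning("hydrogen ", structure$labels[h], " has no bond; unchanged")
      next
    }
    x <- nb[1L]
    if (structure$z[x] == 1L) next
    key <- paste0(sym[x], ".", length(adj[[x]]))
    d_tab <- if (key %in% names(table)) table[[key]]
             else if (sym[x] %in% names(table)) table[[sym[x]]]
             else NA_real_
    if (is.na(d_tab)) {
      warning("no neutron distance for context ", key, "; unchanged")
      next
    }
    v <- structure$xyz[h, ] - structure$xyz[x, ]
    structure$xyz[h, ] <- structure$xyz[x, ] + v / sqrt(sum(v^2)) * d_tab
  }
  structure
}
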