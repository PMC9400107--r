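# Atom typing: matching colored atom-type graphs against molecular graphs
# by graph-subgraph isomorphism, grouping of unassigned atoms, and coverage
# statistics.

#' Compile an atom-type entry into a matchable type graph
#'
#' @param entry An `atom_type_definition`.
#' @return A `type_graph`: igraph pattern + per-vertex colors + root +
#'   depth (max BFS distance from the root).
#' @export
compile_type <- function(entry) {
  rules <- .effective_rules(entry)
  labs <- names(rules)
  edges <- NULL
  for (r in rules) for (b in r$bonded_to) {
    i <- match(r$label, labs); j <- match(b, labs)
    if (is.na(j)) stop("rule ", r$label, " bonds to undefined label ", b)
    if (i < j) edges <- rbind(edges, c(i, j))
    else edges <- rbind(edges, c(j, i))
  }
  edges <- unique(edges)
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(labs),
                          directed = FALSE)
  if (!igraph::is_connected(g)) stop("disconnected type graph in entry ",
                                     entry$type_id)
  root <- match(entry$central, labs)
  depth <- max(igraph::distances(g, v = root)[1L, ])
  structure(list(graph = g, labels = labs, rules = rules, root = root,
                 depth = as.integer(depth),
                 ring_relations = entry$ring_relations,
                 type_id = entry$type_id),
            class = "type_graph")
}

# Does structure atom `i` (with descriptor set d) satisfy the color of
# `rule`?
.color_match <- function(rule, d) {
  if (!is.null(rule$elements) && !d$z %in% rule$elements) return(FALSE)
  if (!is.na(rule$nb) && d$n_neighbors != rule$nb) return(FALSE)
  if (rule$planar == "yes" && !isTRUE(d$planar)) return(FALSE)
  if (rule$planar == "no" && !isFALSE(d$planar)) return(FALSE)
  if (!identical(rule$rings, "any")) {
    if (identical(rule$rings, "none")) {
      if (nrow(d$rings) > 0L) return(FALSE)
    } else {
      for (i in seq_len(nrow(rule$rings))) {
        sz <- as.integer(rule$rings[i, "size"])
        pl <- rule$rings[i, "planar"]
        hit <- d$rings[, "size"] == sz &
          (pl == "a" | (pl == "p" & d$rings[, "planar"] == 1) |
             (pl == "n" & d$rings[, "planar"] == 0))
        if (!any(hit)) return(FALSE)
      }
    }
  }
  TRUE
}

.ring_relations_ok <- function(type_graph, map, descriptors) {
  for (rr in type_graph$ring_relations) {
    ia <- map[[match(rr$a, type_graph$labels)]]
    ib <- map[[match(rr$b, type_graph$labels)]]
    shared <- intersect(descriptors[[ia]]$ring_ids,
                        descriptors[[ib]]$ring_ids)
    if (rr$relation == "same_ring" && !length(shared)) return(FALSE)
    if (rr$relation == "different_ring" &&
        (length(shared) ||
         !length(descriptors[[ia]]$ring_ids) ||
         !length(descriptors[[ib]]$ring_ids))) return(FALSE)
  }
  TRUE
}

# igraph of the whole structure (used as the isomorphism target).
.structure_graph <- function(structure) {
  b <- structure$bonds
  if (is.null(b)) stop("connectivity not built")
  igraph::make_graph(edges = as.vector(t(b)), n = length(structure$z),
                     directed = FALSE)
}

#' Match one type graph against one structure atom
#'
#' Searches for an injective mapping of the type graph into the molecular
#' graph that sends the type's central vertex to `atom`, preserves edges,
#' satisfies every vertex color (element set, neighbor count, planarity,
#' ring membership), and honors the entry's same-ring / different-ring
#' relations (verified after the isomorphism stage).
#'
#' @param type_graph A [compile_type()] result.
#' @param atom Structure atom index the central vertex must map to.
#' @param structure A `molecular_structure` with connectivity.
#' @param descriptors Result of [compute_descriptors()] (recomputed when
#'   omitted).
#' @param target_graph Optional pre-built igraph of the structure.
#' @return Named integer vector (type labels -> atom indices), or `NULL`
#'   when no mapping exists.
#' @export
match_type <- function(type_graph, atom, structure, descriptors = NULL,
                       target_graph = NULL) {
  if (is.null(descriptors)) descriptors <- compute_descriptors(structure)
  if (is.null(target_graph)) target_graph <- .structure_graph(structure)
  nv <- length(type_graph$labels)
  domains <- vector("list", nv)
  for (v in seq_len(nv)) {
    rule <- type_graph$rules[[v]]
    if (v == type_graph$root) {
      cand <- if (.color_match(rule, descriptors[[atom]])) atom
              else integer(0)
    } else {
      cand <- which(vapply(descriptors, function(d) .color_match(rule, d),
                           TRUE))
      cand <- setdiff(cand, atom)
    }
    if (!length(cand)) return(NULL)
    domains[[v]] <- cand
  }
  maps <- igraph::subgraph_isomorphisms(type_graph$graph, target_graph,
                                        method = "lad", induced = FALSE,
                                        domains = domains)
  for (m in maps) {
    map <- as.integer(m)
    if (map[type_graph$root] != atom) next
    if (.ring_relations_ok(type_graph, map, descriptors))
      return(stats::setNames(map, type_graph$labels))
  }
  NULL
}

#' Assign bank atom types over a structure
#'
#' For every asymmetric-unit atom the bank entries are tried in file order
#' and the first matching entry is assigned (detailed-before-general is the
#' bank author's responsibility; see [check_entry_order()]).
#'
#' @param structure A `molecular_structure`; connectivity and descriptors
#'   are computed if missing.  For periodic structures grow the cluster to
#'   at least the bank's maximum type-graph depth first (see
#'   [grow_cluster()] and [bank_depth()]).
#' @param bank A `bank` object.
#' @return A `type_assignment`: list with `type_id` (character per
#'   asymmetric-unit atom, `NA` when unassigned), `atom` (their indices),
#'   `mappings` (list of label -> atom index vectors), `structure` and
#'   `descriptors`.
#' @export
assign_types <- function(structure, bank) {
  if (is.null(structure$bonds)) structure <- build_connectivity(structure)
  if (is.null(structure$rings)) structure <- perceive_rings(structure)
  descriptors <- compute_descriptors(structure)
  tg <- lapply(bank$entries, compile_type)
  target_graph <- .structure_graph(structure)
  asu <- which(structure$in_asu)
  type_id <- rep(NA_character_, length(asu))
  mappings <- vector("list", length(asu))
  for (k in seq_along(asu)) {
    a <- asu[k]
    for (t in seq_along(tg)) {
      m <- match_type(tg[[t]], a, structure, descriptors, target_graph)
      if (!is.null(m)) {
        type_id[k] <- tg[[t]]$type_id
        mappings[[k]] <- m
        break
      }
    }
  }
  structure(list(atom = asu, type_id = type_id, mappings = mappings,
                 structure = structure, descriptors = descriptors),
            class = "type_assignment")
}

#' Maximum type-graph depth of a bank
#'
#' The smallest neighbor-shell count sufficient for correct assignment: the
#' cluster grown around the asymmetric unit must reach at least this depth.
#'
#' @param bank A `bank` object.
#' @return Integer depth.
#' @export
bank_depth <- function(bank) {
  max(vapply(bank$entries, function(e) compile_type(e)$depth, 0L))
}

# --- unassigned grouping and coverage --------------------------------------

.multiset_str <- function(z) {
  if (!length(z)) return("-")
  paste(sort(element_symbol(as.integer(z))), collapse = ",")
}

# Topology key of one unassigned atom.
.group_key <- function(structure, descriptors, adj, i) {
  d <- descriptors[[i]]
  first <- adj[[i]]
  second <- setdiff(unique(unlist(adj[first])), c(i, first))
  ring_s <- if (nrow(d$rings)) {
    o <- order(d$rings[, "size"], d$rings[, "planar"])
    paste(paste0(d$rings[o, "size"],
                 ifelse(d$rings[o, "planar"] == 1, "p", "n")),
          collapse = ",")
  } else "-"
  sprintf("%s|nb1=%s|nb2=%s|planar=%s|rings=%s",
          element_symbol(d$z), .multiset_str(structure$z[first]),
          .multiset_str(structure$z[second]),
          if (is.na(d$planar)) "na" else tolower(d$planar), ring_s)
}

#' Group unassigned atoms by local topology
#'
#' Unassigned asymmetric-unit atoms are keyed by atomic number, the element
#' multisets of their first and second neighbors, group planarity and ring
#' descriptors; groups are sorted by descending size, ties broken by key.
#'
#' @param assignments A `type_assignment` or list of them.
#' @return Data frame with columns `key`, `count`.
#' @export
group_unassigned <- function(assignments) {
  if (inherits(assignments, "type_assignment"))
    assignments <- list(assignments)
  keys <- character(0)
  for (as_ in assignments) {
    un <- as_$atom[is.na(as_$type_id)]
    if (!length(un)) next
    adj <- .adjacency_list(as_$structure)
    keys <- c(keys, vapply(un, function(i)
      .group_key(as_$structure, as_$descriptors, adj, i), ""))
  }
  if (!length(keys))
    return(data.frame(key = character(0), count = integer(0)))
  tab <- table(keys)
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    row.names = NULL)
  out[order(-out$count, out$key), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Coverage statistics over a structure set
#'
#' Assigns types over every structure and reports the statistics a bank
#' curator tracks: per-type atom counts, the fraction of assigned atoms,
#' the fraction of structures with all atoms assigned, and the unassigned
#' topology groups.  Structures containing elements beyond Kr are never
#' counted as fully assigned (their other atoms are still typed).
#'
#' @param structures List of `molecular_structure` objects.
#' @param bank A `bank` object.
#' @return A `coverage_report`: list with `per_type` (data frame `type_id`,
#'   `count`), `n_atoms`, `n_assigned`, `atom_fraction` (percent),
#'   `n_structures`, `n_full`, `structure_fraction` (percent), `groups`
#'   (from [group_unassigned()]) and `assignments`.
#' @export
coverage_stats <- function(structures, bank) {
  if (!length(structures)) stop("empty structure set")
  assignments <- lapply(structures, assign_types, bank = bank)
  n_atoms <- 0L; n_assigned <- 0L; n_full <- 0L
  per <- integer(0)
  for (as_ in assignments) {
    ok <- !is.na(as_$type_id)
    n_atoms <- n_atoms + length(ok)
    n_assigned <- n_assigned + sum(ok)
    eligible <- all(as_$structure$z <= 36L)
    if (all(ok) && eligible) n_full <- n_full + 1L
    t <- table(as_$type_id[ok])
    for (nm in names(t)) per[nm] <- (if (nm %in% names(per)) per[nm]
                                     else 0L) + t[[nm]]
  }
  per_type <- if (length(per))
    data.frame(type_id = names(per), count = as.integer(per),
               row.names = NULL)
  else data.frame(type_id = character(0), count = integer(0))
  per_type <- per_type[order(-per_type$count, per_type$type_id), ,
                       drop = FALSE]
  rownames(per_type) <- NULL
  structure(list(per_type = per_type, n_atoms = n_atoms,
                 n_assigned = n_assigned,
                 atom_fraction = 100 * n_assigned / n_atoms,
                 n_structures = length(structures), n_full = n_full,
                 structure_fraction = 100 * n_full / length(structures),
                 groups = group_unassigned(assignments),
                 assignments = assignments),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("Coverage report\n")
  cat(sprintf("  atoms assigned:      %d / %d (%.2f%%)\n", x$n_assigned,
              x$n_atoms, x$atom_fraction))
  cat(sprintf("  structures complete: %d / %d (%.2f%%)\n", x$n_full,
              x$n_structures, x$structure_fraction))
  if (nrow(x$per_type)) {
    cat("  per-type counts:\n")
    for (i in seq_len(nrow(x$per_type)))
      cat(sprintf("    %-10s %d\n", x$per_type$type_id[i],
                  x$per_type$count[i]))
  }
  if (nrow(x$groups)) {
    cat("  unassigned groups:\n")
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("    %5d  %s\n", x$groups$count[i], x$groups$key[i]))
  }
  invisible(x)
}

#' Coverage gain from newly assigned atoms
#'
#' The percentage-point increase in atom coverage obtained by assigning
#' `n_new` previously unassigned atoms out of `n_total` analyzed atoms.
#'
#' @param n_new Number of newly assigned atoms.
#' @param n_total Total number of analyzed atoms.
#' @return Gain in percentage points.
#' @export
coverage_gain <- function(n_new, n_total) 100 * n_new / n_total
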