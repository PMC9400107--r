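# The pseudoatom data-bank model and its line-oriented text format.
#
# A bank file carries a version header, per-element radial settings, and an
# ordered list of atom-type entries.  Each entry is a colored connectivity
# graph (central atom + neighbor shells with element / planarity / ring
# descriptors), a local-frame definition, a point-group symmetry label and
# the averaged multipole parameters with their sample standard deviations.
#
#   MATTSLIKE 1
#   RADIAL C NL 2 2 2 3 4 ZETA 6.0017 ... VALN 2 VALZ 5.9261
#   ENTRY C330
#   COMMENT aromatic carbon
#   CENTRAL C1
#   ATOM C1 ELEM C BONDS C2,C3,H1 PLANAR yes RINGS 6p
#   ATOM C2 ELEM C BONDS C1 PLANAR any RINGS 6p
#   RINGREL same C2 C3
#   FRAME Z C2 X C3
#   SYMMETRY m
#   PVAL 4.0000 0.0500 12
#   KAPPA 0.9900 0.0050 12
#   KPRIME 0.9200 0.0300 12
#   PLM 1 0 0.0200 0.0100 12
#   END
#
# Ring descriptors: "any", "none", or a comma list of <size><p|n|a>
# (planar / nonplanar / either).  Elements: symbol, comma list, or the
# wildcard "X".  "NB k" pins the neighbor count of a non-central vertex
# (the central atom's neighbor count is always exact).  Entry order is
# meaningful: assignment tries entries first to last, so detailed types
# must precede their generalizations (audited by check_entry_order()).

.fmt4 <- function(x) sprintf("%.4f", x)

.quality_thresholds_default <- list(max_ssd_pval = 0.1, max_ssd_kappa = 0.01,
                                    max_ssd_kappa_prime = 0.1,
                                    max_ssd_plm = 0.05)

#' Connectivity rule (one colored vertex of an atom-type graph)
#'
#' @param label Vertex label, unique within the entry (e.g. `"C1"`).
#' @param elements Allowed element symbols (character vector), or `"X"` for
#'   any element.
#' @param bonded_to Labels of bonded vertices.
#' @param planar `"yes"`, `"no"` or `"any"` (group planarity of the atom).
#' @param rings `"any"`, `"none"`, or a character vector of ring
#'   descriptors `"<size><p|n|a>"` such as `"6p"`.
#' @param nb Required neighbor count in the structure, `NA` for
#'   unconstrained (the central atom is always matched with its exact
#'   listed neighbor count).
#' @return A `connectivity_rule` object.
#' @export
connectivity_rule <- function(label, elements, bonded_to,
                              planar = "any", rings = "any", nb = NA) {
  stopifnot(planar %in% c("yes", "no", "any"))
  if (identical(elements, "X")) {
    elem_z <- NULL
  } else {
    elem_z <- sort(element_number(elements))
  }
  if (length(rings) == 1L && rings %in% c("any", "none")) {
    ring_req <- rings
  } else {
    m <- regmatches(rings, regexec("^([3-9])([pna])$", rings))
    if (any(vapply(m, length, 0L) != 3L))
      stop("bad ring descriptor(s): ", paste(rings, collapse = ","),
           " (expected e.g. '6p', '5a')")
    ring_req <- cbind(size = vapply(m, function(x) as.integer(x[2L]), 0L),
                      planar = vapply(m, `[[`, "", 3L))
  }
  structure(list(label = label, elements = elem_z,
                 bonded_to = as.character(bonded_to), planar = planar,
                 rings = ring_req, nb = if (is.na(nb)) NA_integer_
                                        else as.integer(nb)),
            class = "connectivity_rule")
}

#' Atom-type definition (one bank entry)
#'
#' @param type_id Unique identifier, e.g. `"C330"`.
#' @param central Label of the central atom among `rules`.
#' @param rules List of [connectivity_rule()] objects.
#' @param frame A [frame_spec()].
#' @param symmetry Point-group symbol (see [point_group_symbols()]).
#' @param ring_relations Optional list of `list(relation, a, b)` with
#'   `relation` `"same_ring"` or `"different_ring"`.
#' @param params Parameter block: list with `p_val`, `kappa`, `kappa_prime`
#'   (each `c(mean, ssd, n)`), `plm_mean`, `plm_ssd`, `plm_n` (5 x 9
#'   matrices) and `l_max`.  Defaults to a neutral-atom placeholder.
#' @param comment Free-text comment.
#' @param allow_loose Exempt the entry from the ssd quality thresholds
#'   (atom types with expected large density variation).
#' @return An `atom_type_definition` object (validated).
#' @export
atom_type_definition <- function(type_id, central, rules, frame, symmetry,
                                 ring_relations = list(), params = NULL,
                                 comment = "", allow_loose = FALSE) {
  names(rules) <- vapply(rules, `[[`, "", "label")
  symmetry <- normalize_point_group(symmetry)
  if (is.null(params)) {
    z <- rules[[central]]$elements[1L]
    lm <- if (!is.null(z) && z == 1L) 2L else 4L
    nv <- if (!is.null(z)) tryCatch(n_valence(z), error = function(e) 0)
          else 0
    params <- list(p_val = c(nv, 0, 0), kappa = c(1, 0, 0),
                   kappa_prime = c(1, 0, 0),
                   plm_mean = plm_zero(lm), plm_ssd = plm_zero(lm),
                   plm_n = plm_zero(lm), l_max = lm)
  }
  entry <- structure(list(type_id = type_id, central = central,
                          rules = rules, frame = frame,
                          symmetry = symmetry,
                          ring_relations = ring_relations, params = params,
                          comment = comment, allow_loose = allow_loose),
                     class = "atom_type_definition")
  msg <- validate_entry(entry)
  if (length(msg)) stop("invalid entry '", type_id, "': ",
                        paste(msg, collapse = "; "))
  entry
}

# Structural validation; returns character vector of problems (empty = ok).
validate_entry <- function(entry) {
  out <- character(0)
  labs <- names(entry$rules)
  if (!entry$central %in% labs)
    out <- c(out, "central label not among rules")
  for (r in entry$rules) {
    bad <- setdiff(r$bonded_to, labs)
    if (length(bad))
      out <- c(out, paste0("rule ", r$label, " bonds to undefined label(s) ",
                           paste(bad, collapse = ",")))
  }
  if (length(out)) return(out)
  # connectedness from the central atom
  reach <- entry$central
  repeat {
    nb <- unique(unlist(lapply(entry$rules[reach], `[[`, "bonded_to")))
    nb <- union(nb, labs[vapply(entry$rules, function(r)
      any(reach %in% r$bonded_to), TRUE)])
    grown <- union(reach, nb)
    if (setequal(grown, reach)) break
    reach <- grown
  }
  if (!setequal(reach, labs))
    out <- c(out, paste0("type graph not connected: unreachable ",
                         paste(setdiff(labs, reach), collapse = ",")))
  for (rr in entry$ring_relations) {
    if (!all(c(rr$a, rr$b) %in% labs))
      out <- c(out, "ring relation references undefined label")
    if (!rr$relation %in% c("same_ring", "different_ring"))
      out <- c(out, paste0("unknown ring relation '", rr$relation, "'"))
  }
  ft <- c(entry$frame$axis1$target, entry$frame$axis2$target)
  bad <- setdiff(ft, labs)
  if (length(bad))
    out <- c(out, paste0("frame target(s) not defined: ",
                         paste(bad, collapse = ",")))
  # symmetry selection rules on the stored means
  allowed <- allowed_indices(entry$symmetry, entry$params$l_max)
  akey <- paste(allowed[, "l"], allowed[, "m"])
  idx <- plm_indices(entry$params$l_max)
  for (i in seq_len(nrow(idx))) {
    l <- idx[i, "l"]; m <- idx[i, "m"]
    if (!paste(l, m) %in% akey &&
        abs(plm_get(entry$params$plm_mean, l, m)) > 1e-6)
      out <- c(out, sprintf(
        "P_lm (%d,%+d) is forbidden by symmetry '%s' but nonzero",
        l, m, entry$symmetry))
  }
  out
}

#' Assemble a bank
#'
#' @param entries List of [atom_type_definition()] objects (order is the
#'   assignment order).
#' @param radial Named list per element symbol:
#'   `list(n_l, zeta, val_n, val_zeta)`; defaults are filled from
#'   [radial_model()] and [spherical_atom_density()] for every element used
#'   by the entries.
#' @param version Format version string.
#' @return A `bank` object.
#' @export
bank <- function(entries, radial = NULL, version = "1") {
  ids <- vapply(entries, `[[`, "", "type_id")
  if (anyDuplicated(ids)) stop("duplicate type_id: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  used <- sort(unique(unlist(lapply(entries, function(e)
    unlist(lapply(e$rules, `[[`, "elements"))))))
  need <- element_symbol(used[used %in% element_number(bank_elements())])
  if (is.null(radial)) radial <- list()
  for (el in need) {
    if (is.null(radial[[el]])) {
      rm_ <- radial_model(el)
      sph <- spherical_atom_density(el)
      radial[[el]] <- list(n_l = rm_$n_l, zeta = rm_$zeta,
                           val_n = sph$valence_shell$n_pow,
                           val_zeta = sph$valence_shell$zeta)
    }
  }
  structure(list(version = version, radial = radial, entries = entries),
            class = "bank")
}

#' @export
print.bank <- function(x, ...) {
  cat("<bank> format MATTSLIKE", x$version, "-", length(x$entries),
      "atom types:", paste(vapply(x$entries, `[[`, "", "type_id"),
                           collapse = " "), "\n")
  invisible(x)
}

# --- writer ----------------------------------------------------------------

.ring_str <- function(rings) {
  if (is.character(rings) && length(rings) == 1L) return(rings)
  paste(paste0(rings[, "size"], rings[, "planar"]), collapse = ",")
}

.elem_str <- function(z) {
  if (is.null(z)) "X"
  else paste(element_symbol(as.integer(z)), collapse = ",")
}

.target_str <- function(target) {
  if (length(target) > 1L) paste0("avg(", paste(target, collapse = ","), ")")
  else target
}

.quality_flags <- function(entry,
                           thresholds = .quality_thresholds_default) {
  p <- entry$params
  out <- character(0)
  chk <- function(name, ssd, thr)
    if (ssd > thr) sprintf("# QFLAG %s ssd %s exceeds %s", name,
                           .fmt4(ssd), .fmt4(thr))
  out <- c(out, chk("pval", p$p_val[2L], thresholds$max_ssd_pval),
           chk("kappa", p$kappa[2L], thresholds$max_ssd_kappa),
           chk("kprime", p$kappa_prime[2L], thresholds$max_ssd_kappa_prime))
  idx <- plm_indices(p$l_max)
  for (i in seq_len(nrow(idx))) {
    s <- plm_get(p$plm_ssd, idx[i, "l"], idx[i, "m"])
    if (s > thresholds$max_ssd_plm)
      out <- c(out, sprintf("# QFLAG plm %d %d ssd %s exceeds %s",
                            idx[i, "l"], idx[i, "m"], .fmt4(s),
                            .fmt4(thresholds$max_ssd_plm)))
  }
  out
}

#' Serialize a bank to its canonical text form
#'
#' Canonical: fixed block and field order, populations and kappas to four
#' decimals, so that `write(parse(text))` is a fixpoint.  Parameters whose
#' sample standard deviation exceeds the transferability thresholds get a
#' `# QFLAG` comment line.
#'
#' @param bank A `bank` object.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_bank <- function(bank, path = NULL) {
  for (e in bank$entries) {
    msg <- validate_entry(e)
    if (length(msg)) stop("refusing to serialize invalid entry '",
                          e$type_id, "': ", paste(msg, collapse = "; "))
  }
  out <- paste("MATTSLIKE", bank$version)
  for (el in sort(names(bank$radial))) {
    r <- bank$radial[[el]]
    out <- c(out, paste("RADIAL", el, "NL", paste(r$n_l, collapse = " "),
                        "ZETA", paste(.fmt4(r$zeta), collapse = " "),
                        "VALN", r$val_n, "VALZ", .fmt4(r$val_zeta)))
  }
  for (e in bank$entries) {
    out <- c(out, paste("ENTRY", e$type_id))
    if (nzchar(e$comment)) out <- c(out, paste("COMMENT", e$comment))
    out <- c(out, paste("CENTRAL", e$central))
    for (r in e$rules) {
      ln <- paste("ATOM", r$label, "ELEM", .elem_str(r$elements),
                  "BONDS", paste(r$bonded_to, collapse = ","),
                  "PLANAR", r$planar, "RINGS", .ring_str(r$rings))
      if (!is.na(r$nb)) ln <- paste(ln, "NB", r$nb)
      out <- c(out, ln)
    }
    for (rr in e$ring_relations)
      out <- c(out, paste("RINGREL",
                          sub("_ring$", "", rr$relation), rr$a, rr$b))
    out <- c(out, paste("FRAME", e$frame$axis1$axis,
                        .target_str(e$frame$axis1$target),
                        e$frame$axis2$axis,
                        .target_str(e$frame$axis2$target)))
    out <- c(out, paste("SYMMETRY", e$symmetry))
    if (e$allow_loose) out <- c(out, "LOOSE yes")
    p <- e$params
    if (p$l_max != 4L) out <- c(out, paste("LMAX", p$l_max))
    pv <- function(tag, v) paste(tag, .fmt4(v[1L]), .fmt4(v[2L]),
                                 as.integer(v[3L]))
    out <- c(out, pv("PVAL", p$p_val), pv("KAPPA", p$kappa),
             pv("KPRIME", p$kappa_prime))
    idx <- plm_indices(p$l_max)
    for (i in seq_len(nrow(idx))) {
      l <- idx[i, "l"]; m <- idx[i, "m"]
      mean <- plm_get(p$plm_mean, l, m)
      ssd <- plm_get(p$plm_ssd, l, m)
      n <- plm_get(p$plm_n, l, m)
      if (mean != 0 || ssd != 0)
        out <- c(out, paste("PLM", l, m, .fmt4(mean), .fmt4(ssd),
                            as.integer(n)))
    }
    out <- c(out, .quality_flags(e), "END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# --- parser ----------------------------------------------------------------

.parse_target <- function(s) {
  if (grepl("^avg\\(", s)) strsplit(sub("^avg\\((.*)\\)$", "\\1", s),
                                    ",")[[1L]]
  else s
}

#' Parse a bank file
#'
#' @param x Path to a bank file, or a character vector of lines.
#' @return A `bank` object with entries in file order.
#' @export
parse_bank <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
           else x
  lines_raw <- lines
  strip <- sub("#.*$", "", lines)
  strip <- trimws(strip)
  perr <- function(i, ...) stop("bank parse error at line ", i, ": ", ...,
                                call. = FALSE)
  i1 <- which(nzchar(strip))[1L]
  if (is.na(i1) || !grepl("^MATTSLIKE\\s+\\S+$", strip[i1]))
    perr(1L, "missing 'MATTSLIKE <version>' header")
  version <- strsplit(strip[i1], "\\s+")[[1L]][2L]
  radial <- list()
  entries <- list()
  cur <- NULL; cur_line <- NA_integer_
  finish <- function(cur, i) {
    p <- cur$params
    lm <- cur$l_max %||% {
      z1 <- cur$rules[[cur$central]]$elements[1L]
      if (!is.null(z1) && z1 == 1L) 2L else 4L
    }
    params <- list(p_val = p$pval %||% c(0, 0, 0),
                   kappa = p$kappa %||% c(1, 0, 0),
                   kappa_prime = p$kprime %||% c(1, 0, 0),
                   plm_mean = p$plm_mean %||% plm_zero(lm),
                   plm_ssd = p$plm_ssd %||% plm_zero(lm),
                   plm_n = p$plm_n %||% plm_zero(lm), l_max = lm)
    attr(params$plm_mean, "l_max") <- lm
    entry <- structure(list(type_id = cur$type_id, central = cur$central,
                            rules = cur$rules, frame = cur$frame,
                            symmetry = cur$symmetry,
                            ring_relations = cur$ring_relations,
                            params = params, comment = cur$comment,
                            allow_loose = cur$allow_loose),
                       class = "atom_type_definition")
    msg <- validate_entry(entry)
    attr(entry, "diagnostics") <- msg
    entry
  }
  for (i in seq_along(strip)) {
    ln <- strip[i]
    if (!nzchar(ln) || i == i1) next
    t <- strsplit(ln, "\\s+")[[1L]]
    key <- toupper(t[1L])
    if (is.null(cur)) {
      if (key == "RADIAL") {
        if (length(t) < 17L) perr(i, "short RADIAL record")
        radial[[t[2L]]] <- list(n_l = as.integer(t[4:8]),
                                zeta = as.numeric(t[10:14]),
                                val_n = as.integer(t[16L]),
                                val_zeta = as.numeric(t[18L]))
      } else if (key == "ENTRY") {
        cur <- list(type_id = t[2L], comment = "", rules = list(),
                    ring_relations = list(), allow_loose = FALSE,
                    params = list(), l_max = NULL)
        cur_line <- i
      } else perr(i, "unexpected record '", t[1L], "' outside an entry")
    } else {
      eid <- cur$type_id
      switch(key,
        COMMENT = { cur$comment <- sub("^\\s*COMMENT\\s+", "", ln) },
        CENTRAL = { cur$central <- t[2L] },
        ATOM = {
          kv <- t[-(1:2)]
          fields <- list()
          j <- 1L
          while (j < length(kv)) {
            fields[[toupper(kv[j])]] <- kv[j + 1L]; j <- j + 2L
          }
          elems <- if (identical(fields$ELEM, "X")) "X"
                   else strsplit(fields$ELEM %||% "X", ",")[[1L]]
          rings <- fields$RINGS %||% "any"
          if (!rings %in% c("any", "none"))
            rings <- strsplit(rings, ",")[[1L]]
          rule <- tryCatch(
            connectivity_rule(t[2L], elems,
                              strsplit(fields$BONDS %||% "", ",")[[1L]],
                              planar = fields$PLANAR %||% "any",
                              rings = rings,
                              nb = as.integer(fields$NB %||% NA)),
            error = function(e) perr(i, "entry ", eid, ": ",
                                     conditionMessage(e)))
          cur$rules[[t[2L]]] <- rule
        },
        RINGREL = {
          cur$ring_relations[[length(cur$ring_relations) + 1L]] <-
            list(relation = paste0(t[2L], "_ring"), a = t[3L], b = t[4L])
        },
        FRAME = {
          cur$frame <- frame_spec(t[2L], .parse_target(t[3L]),
                                  t[4L], .parse_target(t[5L]))
        },
        SYMMETRY = {
          cur$symmetry <- tryCatch(normalize_point_group(t[2L]),
                                   error = function(e)
                                     perr(i, "entry ", eid, ": ",
                                          conditionMessage(e)))
        },
        LOOSE = { cur$allow_loose <- identical(tolower(t[2L]), "yes") },
        LMAX = { cur$l_max <- as.integer(t[2L]) },
        PVAL = { cur$params$pval <- as.numeric(t[2:4]) },
        KAPPA = { cur$params$kappa <- as.numeric(t[2:4]) },
        KPRIME = { cur$params$kprime <- as.numeric(t[2:4]) },
        PLM = {
          l <- as.integer(t[2L]); m <- as.integer(t[3L])
          if (is.na(l) || is.na(m) || abs(m) > l)
            perr(i, "entry ", eid, ": bad PLM index")
          if (is.null(cur$params$plm_mean)) {
            cur$params$plm_mean <- plm_zero()
            cur$params$plm_ssd <- plm_zero()
            cur$params$plm_n <- plm_zero()
          }
          cur$params$plm_mean <- plm_set(cur$params$plm_mean, l, m,
                                         as.numeric(t[4L]))
          cur$params$plm_ssd <- plm_set(cur$params$plm_ssd, l, m,
                                        as.numeric(t[5L]))
          cur$params$plm_n <- plm_set(cur$params$plm_n, l, m,
                                      as.numeric(t[6L]))
        },
        END = {
          entries[[length(entries) + 1L]] <- finish(cur, i)
          cur <- NULL
        },
        perr(i, "entry ", eid, ": unknown record '", t[1L], "'")
      )
    }
  }
  if (!is.null(cur)) perr(length(strip),
                          "entry '", cur$type_id, "' not terminated by END")
  ids <- vapply(entries, `[[`, "", "type_id")
  if (anyDuplicated(ids))
    stop("duplicate type_id in bank: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  b <- structure(list(version = version, radial = radial,
                      entries = entries), class = "bank")
  .check_bank_radial(b)
  b
}

.check_bank_radial <- function(b) {
  used <- unique(unlist(lapply(b$entries, function(e)
    unlist(lapply(e$rules, `[[`, "elements")))))
  used <- used[used %in% element_number(bank_elements())]
  miss <- setdiff(element_symbol(as.integer(used)), names(b$radial))
  if (length(miss))
    warning("bank header lacks RADIAL settings for element(s): ",
            paste(miss, collapse = ", "))
  invisible(b)
}

#' Validation report for a parsed bank
#'
#' @param bank A `bank` object.
#' @return Character vector, one diagnostic per line (empty when clean).
#' @export
bank_diagnostics <- function(bank) {
  out <- character(0)
  for (e in bank$entries) {
    d <- attr(e, "diagnostics")
    if (length(d)) out <- c(out, paste0(e$type_id, ": ", d))
  }
  out
}

# --- entry-order audit -----------------------------------------------------

# TRUE when color of rule `a` is equal or more permissive than color of `b`.
.color_generalizes <- function(a, b) {
  if (!is.null(a$elements)) {
    if (is.null(b$elements)) return(FALSE)
    if (!all(b$elements %in% a$elements)) return(FALSE)
  }
  if (a$planar != "any" && a$planar != b$planar) return(FALSE)
  if (!identical(a$rings, "any")) {
    if (identical(a$rings, "none")) {
      if (!identical(b$rings, "none")) return(FALSE)
    } else {
      if (is.character(b$rings)) return(FALSE)
      for (i in seq_len(nrow(a$rings))) {
        hit <- b$rings[, "size"] == a$rings[i, "size"] &
          (a$rings[i, "planar"] == "a" |
             b$rings[, "planar"] == a$rings[i, "planar"])
        if (!any(hit)) return(FALSE)
      }
    }
  }
  nb_a <- a$nb; nb_b <- b$nb
  if (!is.na(nb_a) && (is.na(nb_b) || nb_a != nb_b)) return(FALSE)
  TRUE
}

# Effective rule with the central-atom exact-degree convention applied.
.effective_rules <- function(entry) {
  rules <- entry$rules
  ce <- rules[[entry$central]]
  if (is.na(ce$nb)) rules[[entry$central]]$nb <-
      length(ce$bonded_to)
  rules
}

# TRUE when entry A is equal to or more general than entry B: A's colored
# graph maps injectively into B's with root on root, edges preserved and
# every A-color at least as permissive as the matched B-color.
.entry_generalizes <- function(A, B) {
  ra <- .effective_rules(A); rb <- .effective_rules(B)
  la <- names(ra); lb <- names(rb)
  if (length(la) > length(lb)) return(FALSE)
  adj <- function(rules) {
    lapply(rules, function(r) r$bonded_to)
  }
  aa <- adj(ra); ab <- adj(rb)
  assign_rec <- function(map) {
    if (length(map) == length(la)) return(TRUE)
    v <- setdiff(la, names(map))[1L]
    for (w in setdiff(lb, unlist(map))) {
      if (!.color_generalizes(ra[[v]], rb[[w]])) next
      ok <- TRUE
      for (u in intersect(aa[[v]], names(map)))
        if (!map[[u]] %in% ab[[w]]) { ok <- FALSE; break }
      if (!ok) next
      map2 <- map; map2[[v]] <- w
      if (assign_rec(map2)) return(TRUE)
    }
    FALSE
  }
  if (!.color_generalizes(ra[[A$central]], rb[[B$central]])) return(FALSE)
  assign_rec(stats::setNames(list(B$central), A$central))
}

#' Audit bank entry order
#'
#' Assignment tries entries in file order, so an entry that is more general
#' than a later one shadows it.  For every ordered pair (A before B) where
#' A's colored type graph maps into B's with equal-or-more-permissive
#' colors, a warning string is emitted.
#'
#' @param bank A `bank` object.
#' @return Character vector of warnings (empty when the order is sound).
#' @export
check_entry_order <- function(bank) {
  out <- character(0)
  n <- length(bank$entries)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    A <- bank$entries[[i]]; B <- bank$entries[[j]]
    if (.entry_generalizes(A, B))
      out <- c(out, sprintf(
        "entry '%s' (position %d) is more general than '%s' (position %d) and will shadow it",
        A$type_id, i, B$type_id, j))
  }
  out
}
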