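# Turning per-atom fitted multipole parameters into averaged, transferable
# atom-type entries: frame reorientation, averaging with sample standard
# deviations, transferability thresholds and the charge / kappa regression.

#' Reorient an instance's populations into the type frame
#'
#' Populations refined in the instance's local frame are re-expressed in
#' the frame defined by the atom-type entry; `P_val`, `kappa` and
#' `kappa_prime` are frame-invariant and pass through unchanged.
#'
#' @param instance A `parameter_instance` (fields `params`, `frame`), or
#'   any list with those fields.
#' @param type_frame The target `local_frame` (or its 3 x 3 rotation).
#' @return A [multipole_parameters()] object in the type frame.
#' @export
reorient_instance <- function(instance, type_frame = local_frame()) {
  R_t <- if (is.matrix(type_frame)) type_frame else type_frame$rotation
  R_i <- instance$frame$rotation
  p <- instance$params
  plm <- rotate_plm(p$plm, t(R_t) %*% R_i)
  attr(plm, "l_max") <- p$l_max
  multipole_parameters(p$p_val, p$kappa, p$kappa_prime, plm,
                       l_max = p$l_max)
}

#' Average parameter instances into a bank entry parameter block
#'
#' Arithmetic means and sample (n - 1) standard deviations are computed per
#' parameter over the (reoriented) instances; populations forbidden by the
#' entry's point-group symmetry are forced to zero after averaging.
#'
#' @param instances List of `parameter_instance` objects.
#' @param entry The target `atom_type_definition` (provides symmetry and
#'   `l_max`); its frame is the reference frame.
#' @param reorient Reorient each instance into the type frame first
#'   (disable when instances are already expressed there).
#' @return An updated copy of `entry` with averaged `params`.
#' @export
average_type <- function(instances, entry, reorient = TRUE) {
  if (!length(instances)) stop("zero instances: nothing to average")
  lm <- entry$params$l_max
  ps <- lapply(instances, function(ins) {
    if (reorient) reorient_instance(ins, local_frame()) else ins$params
  })
  n <- length(ps)
  ssd <- function(x) if (length(x) <= 1L) 0 else stats::sd(x)
  vec3 <- function(x) c(mean(x), ssd(x), n)
  pv <- vec3(vapply(ps, `[[`, 0, "p_val"))
  ka <- vec3(vapply(ps, `[[`, 0, "kappa"))
  kp <- vec3(vapply(ps, `[[`, 0, "kappa_prime"))
  pm <- plm_zero(lm); sm <- plm_zero(lm); nm <- plm_zero(lm)
  allowed <- allowed_indices(entry$symmetry, lm)
  akey <- paste(allowed[, "l"], allowed[, "m"])
  idx <- plm_indices(lm)
  for (i in seq_len(nrow(idx))) {
    l <- idx[i, "l"]; m <- idx[i, "m"]
    x <- vapply(ps, function(p) plm_get(p$plm, l, m), 0)
    if (!paste(l, m) %in% akey) next  # symmetry-forbidden: stays 0
    if (all(x == 0)) next
    pm <- plm_set(pm, l, m, mean(x))
    sm <- plm_set(sm, l, m, ssd(x))
    nm <- plm_set(nm, l, m, n)
  }
  entry$params <- list(p_val = pv, kappa = ka, kappa_prime = kp,
                       plm_mean = pm, plm_ssd = sm, plm_n = nm, l_max = lm)
  entry
}

#' Transferability quality thresholds
#'
#' The desired upper bounds on sample standard deviations of averaged
#' parameters: 0.1 e for `P_val` and `kappa'`, 0.01 for `kappa`, 0.05 e for
#' every `P_lm`.
#'
#' @param max_ssd_pval,max_ssd_kappa,max_ssd_kappa_prime,max_ssd_plm
#'   Override individual bounds.
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function(max_ssd_pval = 0.1, max_ssd_kappa = 0.01,
                               max_ssd_kappa_prime = 0.1,
                               max_ssd_plm = 0.05) {
  stopifnot(max_ssd_pval > 0, max_ssd_kappa > 0, max_ssd_kappa_prime > 0,
            max_ssd_plm > 0)
  list(max_ssd_pval = max_ssd_pval, max_ssd_kappa = max_ssd_kappa,
       max_ssd_kappa_prime = max_ssd_kappa_prime,
       max_ssd_plm = max_ssd_plm)
}

#' Check an averaged entry against the transferability thresholds
#'
#' @param entry An averaged `atom_type_definition`.
#' @param thresholds From [quality_thresholds()].
#' @return List with `pass` (logical; entries flagged `allow_loose` pass
#'   regardless, with violations still listed) and `violations` (data frame
#'   `parameter`, `ssd`, `threshold`).
#' @export
quality_check <- function(entry, thresholds = quality_thresholds()) {
  p <- entry$params
  v <- list()
  add <- function(name, ssd, thr) {
    if (ssd > thr)
      v[[length(v) + 1L]] <<- data.frame(parameter = name, ssd = ssd,
                                         threshold = thr)
  }
  add("p_val", p$p_val[2L], thresholds$max_ssd_pval)
  add("kappa", p$kappa[2L], thresholds$max_ssd_kappa)
  add("kappa_prime", p$kappa_prime[2L], thresholds$max_ssd_kappa_prime)
  idx <- plm_indices(p$l_max)
  for (i in seq_len(nrow(idx))) {
    l <- idx[i, "l"]; m <- idx[i, "m"]
    add(sprintf("plm(%d,%+d)", l, m), plm_get(p$plm_ssd, l, m),
        thresholds$max_ssd_plm)
  }
  violations <- if (length(v)) do.call(rbind, v)
                else data.frame(parameter = character(0), ssd = numeric(0),
                                threshold = numeric(0))
  list(pass = nrow(violations) == 0L || isTRUE(entry$allow_loose),
       violations = violations)
}

#' Regression of expansion-contraction parameters on monopole charges
#'
#' Ordinary least squares of `kappa` (and `kappa'`) on the monopole-derived
#' charge `q = n_val - P_val` across bank entries, per element class:
#' hydrogen types, all non-hydrogen types, and each element separately.
#'
#' @param bank A `bank` object.
#' @param min_entries Smallest class size accepted (default 3).
#' @return Data frame with one row per (class, parameter): `class`,
#'   `parameter`, `n`, `slope`, `intercept`, `r_squared`.
#' @export
q_kappa_analysis <- function(bank, min_entries = 3L) {
  rows <- lapply(bank$entries, function(e) {
    z <- e$rules[[e$central]]$elements[1L]
    if (is.null(z)) return(NULL)
    sym <- element_symbol(z)
    if (!sym %in% bank_elements()) return(NULL)
    data.frame(element = sym, q = monopole_charge(e$params$p_val[1L],
                                                  n_valence(sym)),
               kappa = e$params$kappa[1L],
               kappa_prime = e$params$kappa_prime[1L])
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || !nrow(d)) stop("bank has no entries with a definite ",
                                   "central element")
  classes <- c(list(hydrogen = d[d$element == "H", ],
                    non_hydrogen = d[d$element != "H", ]),
               split(d, d$element))
  out <- list()
  for (cl in names(classes)) {
    dc <- classes[[cl]]
    if (nrow(dc) < min_entries) next
    for (par in c("kappa", "kappa_prime")) {
      fit <- stats::lm(stats::reformulate("q", par), data = dc)
      y <- dc[[par]]
      ss_tot <- sum((y - mean(y))^2)
      # a constant response carries no explainable variance
      r2 <- if (ss_tot < 1e-20) 0
            else 1 - sum(stats::residuals(fit)^2) / ss_tot
      out[[length(out) + 1L]] <- data.frame(
        class = cl, parameter = par, n = nrow(dc),
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        r_squared = r2)
    }
  }
  if (!length(out)) stop("no class reaches ", min_entries, " entries")
  do.call(rbind, out)
}
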