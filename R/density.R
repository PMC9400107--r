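# Evaluation of the pseudoatom (Hansen-Coppens) electron density:
# frozen core + kappa-scaled spherical valence + multipolar deformation.

#' Single-pseudoatom multipole parameter set
#'
#' @param p_val Valence monopole population (electrons).
#' @param kappa Valence expansion-contraction parameter (> 0).
#' @param kappa_prime Deformation contraction parameter (> 0).
#' @param plm Population table from [plm_zero()] (electrons).
#' @param l_max Highest multipole order (4 for non-H, 2 for H).
#' @return An object of class `multipole_parameters`.
#' @export
multipole_parameters <- function(p_val, kappa = 1, kappa_prime = 1,
                                 plm = plm_zero(l_max), l_max = 4L) {
  stopifnot(is.finite(p_val), kappa > 0, kappa_prime > 0)
  idx <- plm_indices(4L)
  bad <- idx[idx[, "l"] > l_max, , drop = FALSE]
  for (i in seq_len(nrow(bad)))
    if (plm_get(plm, bad[i, "l"], bad[i, "m"]) != 0)
      stop("population at l = ", bad[i, "l"], " exceeds l_max = ", l_max)
  structure(list(p_val = p_val, kappa = kappa, kappa_prime = kappa_prime,
                 plm = plm, l_max = as.integer(l_max)),
            class = "multipole_parameters")
}

#' Pseudoatom electron density at arbitrary points
#'
#' Evaluates `rho(r) = rho_core(r) + P_val kappa^3 rho_val(kappa r)/n_val +
#' sum_l R_l(kappa'; r) sum_m P_lm d_lm(u)` where `u` is the direction of
#' the point in the atom's local frame.  The spherical valence shape is
#' normalized per electron so that the valence density integrates exactly
#' to `P_val` when no deformation terms are present.
#'
#' @param params A [multipole_parameters()] object.
#' @param sph A [spherical_atom_density()] object.
#' @param radial A [radial_model()] object for the deformation terms.
#' @param frame A `local_frame` (origin + rotation).
#' @param points Numeric 3-vector or `n x 3` matrix of Cartesian points
#'   (Angstrom).
#' @param include_core Set `FALSE` for the valence-only density.
#' @return Density values in e/Angstrom^3.
#' @export
hc_density <- function(params, sph, radial, frame, points,
                       include_core = TRUE) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3L)
  d <- sweep(points, 2L, frame$origin)
  r <- sqrt(rowSums(d^2))
  out <- numeric(nrow(points))
  if (include_core) out <- out + rho_core(sph, r)
  k <- params$kappa
  out <- out + params$p_val * k^3 * rho_valence(sph, k * r) / sph$n_val
  plm <- params$plm
  if (any(plm != 0)) {
    u <- d %*% frame$rotation          # rows = R^T (p - o)
    pos <- r > 0
    u[pos, ] <- u[pos, , drop = FALSE] / r[pos]
    if (any(!pos)) u[!pos, ] <- matrix(c(0, 0, 1), sum(!pos), 3L,
                                       byrow = TRUE)
    for (l in 0:params$l_max) {
      pl <- plm[l + 1L, (5L - l):(5L + l)]
      if (all(pl == 0)) next
      ang <- numeric(nrow(points))
      for (m in seq.int(-l, l)) {
        p <- unname(pl[m + l + 1L])
        if (p != 0) ang <- ang + p * real_spherical_harmonic(l, m, u)
      }
      rad <- slater_radial(l, r, radial, params$kappa_prime)
      # radial limit at the nucleus: R_l(0) = 0 for n_l >= 1
      rad[!is.finite(rad)] <- 0
      out <- out + rad * ang
    }
  }
  out
}

#' Monopole-derived atomic charge
#'
#' @param p_val Valence monopole population (electrons).
#' @param n_val Valence-electron count of the neutral element (see
#'   [n_valence()]).
#' @return Net atomic charge `q = n_val - P_val` in electrons.
#' @export
monopole_charge <- function(p_val, n_val) n_val - p_val
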