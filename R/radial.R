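# Slater deformation radial functions and their closed-form Fourier-Bessel
# transforms, the quantities behind aspherical atomic form factors.

#' Normalized Slater deformation radial function
#'
#' `R_l(r) = N (kappa' zeta_l)^(n_l + 3) / (n_l + 2)! * r^n_l *
#' exp(-kappa' zeta_l r)`, normalized so that the radial integral
#' `int R_l r^2 dr = 1` for every `kappa'`; the contraction parameter
#' rescales the argument as `kappa' r` with a `kappa'^3` prefactor, which
#' preserves the normalization.
#'
#' @param l Multipole order 0..4 (selects `n_l`, `zeta_l`).
#' @param r Radii (Angstrom), vectorized.
#' @param radial_model A [radial_model()] object.
#' @param kappa_prime Deformation contraction parameter (> 0).
#' @return `R_l(r)` in Angstrom^-3.
#' @export
slater_radial <- function(l, r, radial_model, kappa_prime = 1) {
  stopifnot(l >= 0L, l <= 4L, kappa_prime > 0)
  n <- radial_model$n_l[l + 1L]
  zp <- kappa_prime * radial_model$zeta[l + 1L]
  zp^(n + 3) / factorial(n + 2) * r^n * exp(-zp * r)
}

# Spherical Bessel functions j_l as trigonometric coefficient tables:
# j_l(x) = sum_p S[p] x^-p sin(x) + sum_p C[p] x^-p cos(x), names = power p.
.sphbessel_trig <- list(
  list(s = c("1" = 1), c = numeric(0)),
  list(s = c("2" = 1), c = c("1" = -1)),
  list(s = c("3" = 3, "1" = -1), c = c("2" = -3)),
  list(s = c("4" = 15, "2" = -6), c = c("3" = -15, "1" = 1)),
  list(s = c("5" = 105, "3" = -45, "1" = 1), c = c("4" = -105, "2" = 10))
)

# I(n, a, b, l) = int_0^inf r^(n+2) exp(-a r) j_l(b r) dr, exact for
# integer n >= l.  Two branches guard against cancellation:
#  - power series in (b/a) for small b (the trig form subtracts nearly
#    equal large terms there),
#  - term-by-term Laplace transforms of the trig expansion otherwise,
#    using int r^k exp(-ar) sin(br) dr = k! Im (a - ib)^-(k+1).
# Vectorized over b.
fourier_bessel_slater <- function(n, a, b, l) {
  if (n < l) stop("Fourier-Bessel transform requires n_l >= l")
  out <- numeric(length(b))
  small <- b <= 0.4 * a
  if (any(small)) out[small] <- .fbs_series(n, a, b[small], l)
  if (any(!small)) out[!small] <- .fbs_trig(n, a, b[!small], l)
  out
}

.fbs_series <- function(n, a, b, l) {
  # j_l(x) = sum_k (-1)^k x^(l+2k) / (2^k k! (2l+2k+1)!!)
  acc <- numeric(length(b))
  # log double factorial: (2m+1)!! = (2m+1)! / (2^m m!)
  ldfact <- function(m) lgamma(2 * m + 2) - m * log(2) - lgamma(m + 1)
  for (k in 0:60) {
    lc <- lgamma(n + 3 + l + 2 * k) - k * log(2) - lgamma(k + 1) -
      ldfact(l + k)
    term <- (-1)^k * exp(lc + (l + 2 * k) * log(b) -
                           (n + 3 + l + 2 * k) * log(a))
    term[b == 0] <- if (l + 2 * k == 0) exp(lc - (n + 3) * log(a)) else 0
    acc <- acc + term
    if (k > 2 && all(abs(term) <= 1e-18 * (abs(acc) + 1e-300))) break
  }
  acc
}

.fbs_trig <- function(n, a, b, l) {
  co <- .sphbessel_trig[[l + 1L]]
  w <- complex(real = a, imaginary = -b)
  acc <- numeric(length(b))
  for (p in names(co$s)) {
    k <- n + 2L - as.integer(p)
    acc <- acc + co$s[[p]] * b^(-as.integer(p)) *
      factorial(k) * Im(w^(-(k + 1L)))
  }
  for (p in names(co$c)) {
    k <- n + 2L - as.integer(p)
    acc <- acc + co$c[[p]] * b^(-as.integer(p)) *
      factorial(k) * Re(w^(-(k + 1L)))
  }
  acc
}

#' Fourier-Bessel transform of the deformation radial function
#'
#' `<j_l>(H) = int R_l(kappa'; r) j_l(2 pi H r) r^2 dr` in closed form,
#' where `H = |h*|` is the reciprocal-vector length (`2 sin(theta)/lambda`
#' ... in Angstrom^-1, i.e. `H = 2 s`).  `<j_0>(0) = 1`; transforms with
#' `l >= 1` vanish at the origin.
#'
#' @param l Multipole order 0..4.
#' @param H Reciprocal-vector lengths (Angstrom^-1), vectorized.
#' @param radial_model A [radial_model()] object.
#' @param kappa_prime Contraction parameter.
#' @return Numeric vector of transform values.
#' @export
slater_jl <- function(l, H, radial_model, kappa_prime = 1) {
  n <- radial_model$n_l[l + 1L]
  zp <- kappa_prime * radial_model$zeta[l + 1L]
  zp^(n + 3) / factorial(n + 2) *
    fourier_bessel_slater(n, zp, 2 * pi * H, l)
}

# d <j_l> / d kappa' (analytic; used by the refinement Jacobian).
slater_jl_dkp <- function(l, H, radial_model, kappa_prime = 1) {
  n <- radial_model$n_l[l + 1L]
  z <- radial_model$zeta[l + 1L]
  zp <- kappa_prime * z
  b <- 2 * pi * H
  val <- zp^(n + 3) / factorial(n + 2) * fourier_bessel_slater(n, zp, b, l)
  dIda <- -fourier_bessel_slater(n + 1L, zp, b, l)
  z * ((n + 3) / zp * val + zp^(n + 3) / factorial(n + 2) * dIda)
}

# Scattering factor of a normalized (one-electron) Slater shell, f(0) = 1.
.shell_form_factor <- function(n_pow, zeta, H) {
  zeta^(n_pow + 3) / factorial(n_pow + 2) *
    fourier_bessel_slater(n_pow, zeta, 2 * pi * H, 0L)
}

#' Normalized valence scattering factor
#'
#' Scattering factor of the spherical valence density scaled by the
#' expansion-contraction parameter `kappa`: the transform of
#' `kappa^3 rho_val(kappa r) / n_val`, i.e. `f(H / kappa)` with `f(0) = 1`.
#'
#' @param sph A [spherical_atom_density()] object.
#' @param H Reciprocal-vector lengths (Angstrom^-1).
#' @param kappa Valence expansion-contraction parameter.
#' @return Numeric vector; multiply by `P_val` for the monopole
#'   contribution to the valence-only form factor.
#' @export
valence_form_factor <- function(sph, H, kappa = 1) {
  vs <- sph$valence_shell
  .shell_form_factor(vs$n_pow, vs$zeta, H / kappa)
}

# d f_val(H/kappa) / d kappa (analytic).
valence_form_factor_dk <- function(sph, H, kappa = 1) {
  vs <- sph$valence_shell
  Hk <- H / kappa
  # d f(x)/dx with x = H/kappa; f' (x) = -2 pi N * I(n+1, zeta, 2 pi x, 1)
  fp <- -2 * pi * vs$zeta^(vs$n_pow + 3) / factorial(vs$n_pow + 2) *
    fourier_bessel_slater(vs$n_pow + 1L, vs$zeta, 2 * pi * Hk, 1L)
  fp * (-H / kappa^2)
}

#' Core scattering factor
#'
#' Scattering factor of the frozen-core density (electron units; tends to
#' `n_core` at `H = 0`).  Needed when full rather than valence-only
#' structure factors are requested.
#'
#' @inheritParams valence_form_factor
#' @return Numeric vector.
#' @export
core_form_factor <- function(sph, H) {
  out <- numeric(length(H))
  cs <- sph$core_shells
  for (i in seq_len(nrow(cs)))
    out <- out + cs$n_el[i] * .shell_form_factor(cs$n_pow[i], cs$zeta[i], H)
  out
}
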