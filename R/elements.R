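# Element tables for the first four rows (H..Kr), valence-electron counts,
# and the built-in single-zeta spherical atom densities.

BOHR <- 0.52917721067  # Angstrom per bohr

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

#' Element symbol to atomic number (H..Kr)
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Integer vector of atomic numbers.
#' @export
element_number <- function(symbol) {
  s <- paste0(toupper(substr(symbol, 1L, 1L)),
              tolower(substr(symbol, 2L, nchar(symbol))))
  z <- match(s, .element_symbols)
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(unique(symbol[is.na(z)]), collapse = ", "))
  z
}

#' Atomic number to element symbol
#' @param z Integer vector of atomic numbers, 1..36.
#' @return Character vector of symbols.
#' @export
element_symbol <- function(z) {
  if (any(z < 1L | z > 36L)) stop("atomic number outside 1..36")
  .element_symbols[z]
}

# Valence-electron counts for the bank-covered elements.
.n_val_table <- c(H = 1, C = 4, N = 5, O = 6, F = 7,
                  P = 5, S = 6, Cl = 7, Br = 7)

#' Valence-electron count of a bank-covered element
#' @param element Element symbol or atomic number.
#' @return Number of valence electrons (the neutral-atom monopole
#'   population).
#' @export
n_valence <- function(element) {
  sym <- if (is.numeric(element)) element_symbol(element) else element
  v <- .n_val_table[sym]
  if (anyNA(v)) stop("no valence-electron entry for element: ",
                     paste(sym[is.na(v)], collapse = ", "))
  unname(v)
}

#' Elements covered by pseudoatom banks
#' @return Character vector of element symbols.
#' @export
bank_elements <- function() names(.n_val_table)

# --- single-zeta spherical densities ---------------------------------------

# Orbital exponents (bohr^-1) for the valence shell, Clementi-Raimondi style
# single-zeta values; the density exponent is twice the orbital exponent.
.valence_orbital_zeta <- c(H = 1.000, C = 1.568, N = 1.917, O = 2.227,
                           F = 2.550, P = 1.629, S = 1.827, Cl = 2.039,
                           Br = 2.257)
# Principal quantum number of the valence shell.
.valence_n <- c(H = 1, C = 2, N = 2, O = 2, F = 2, P = 3, S = 3, Cl = 3,
                Br = 4)

# Slater shielding rules for core shells: (shell label, electrons, n).
.core_config <- function(z) {
  sym <- element_symbol(z)
  shells <- list()
  add <- function(n_el, n_principal, zeta_orb) {
    shells[[length(shells) + 1L]] <<-
      list(n_el = n_el, n_principal = n_principal, zeta_orb = zeta_orb)
  }
  if (z > 2) add(2, 1, (z - 0.30) / 1)                     # 1s
  if (z > 10) add(8, 2, (z - 2 * 0.85 - 7 * 0.35) / 2)      # 2s2p
  if (z > 18) {
    add(8, 3, (z - 2 - 8 * 0.85 - 7 * 0.35) / 3)            # 3s3p
    if (z > 30) add(10, 3, (z - 18 - 9 * 0.35) / 3)         # 3d
  }
  if (z %in% c(1, 2)) shells <- list()
  shells
}

#' Built-in spherical atom density (single-zeta Slater shells)
#'
#' Constructs the frozen-core and spherical-valence radial densities used by
#' the pseudoatom model.  Each shell is a normalized Slater density
#' `rho(r) = n_el * zeta^(n+3) / (4 pi (n+2)!) * r^n * exp(-zeta r)` with
#' `n = 2 (n_principal - 1)` and a density exponent of twice the orbital
#' exponent, so core and valence integrate exactly to their electron counts.
#' The object is a documented single-zeta approximation; callers may supply
#' their own shell tables through `core_shells` / `valence_shell` to plug in
#' external tabulations.
#'
#' @param element Element symbol or atomic number (bank-covered elements).
#' @param core_shells Optional data.frame with columns `n_el`, `n_pow`,
#'   `zeta` (Angstrom^-1) overriding the built-in core.
#' @param valence_shell Optional list with `n_pow` and `zeta` (Angstrom^-1)
#'   overriding the built-in valence shell.
#' @return An object of class `spherical_atom_density` with elements
#'   `element`, `z`, `n_core`, `n_val`, `core_shells`, `valence_shell`.
#' @export
spherical_atom_density <- function(element, core_shells = NULL,
                                   valence_shell = NULL) {
  z <- if (is.numeric(element)) as.integer(element) else element_number(element)
  sym <- element_symbol(z)
  nv <- n_valence(sym)
  if (is.null(core_shells)) {
    cfg <- .core_config(z)
    core_shells <- do.call(rbind, lapply(cfg, function(s)
      data.frame(n_el = s$n_el, n_pow = 2L * (s$n_principal - 1L),
                 zeta = 2 * s$zeta_orb / BOHR)))
    if (is.null(core_shells))
      core_shells <- data.frame(n_el = numeric(0), n_pow = integer(0),
                                zeta = numeric(0))
  }
  if (is.null(valence_shell))
    valence_shell <- list(n_pow = 2L * (.valence_n[[sym]] - 1L),
                          zeta = 2 * .valence_orbital_zeta[[sym]] / BOHR)
  structure(list(element = sym, z = z,
                 n_core = sum(core_shells$n_el), n_val = nv,
                 core_shells = core_shells, valence_shell = valence_shell),
            class = "spherical_atom_density")
}

# Normalized Slater shell density (one electron): value at radius r.
.slater_shell_density <- function(r, n_pow, zeta) {
  zeta^(n_pow + 3) / (4 * pi * factorial(n_pow + 2)) * r^n_pow * exp(-zeta * r)
}

#' Frozen-core radial density
#' @param sph A [spherical_atom_density()] object.
#' @param r Radii (Angstrom).
#' @return Density in e/Angstrom^3.
#' @export
rho_core <- function(sph, r) {
  out <- numeric(length(r))
  cs <- sph$core_shells
  for (i in seq_len(nrow(cs)))
    out <- out + cs$n_el[i] * .slater_shell_density(r, cs$n_pow[i], cs$zeta[i])
  out
}

#' Spherical valence radial density (normalized to `n_val` electrons)
#' @inheritParams rho_core
#' @return Density in e/Angstrom^3.
#' @export
rho_valence <- function(sph, r) {
  vs <- sph$valence_shell
  sph$n_val * .slater_shell_density(r, vs$n_pow, vs$zeta)
}

# --- default deformation radial models -------------------------------------

# Slater powers n_l for l = 0..4 and a single deformation exponent per
# element (Angstrom^-1; values are twice the single-zeta orbital exponents,
# quoted in the literature in bohr^-1).  Sulfur uses (2,4,6,8) and
# phosphorus (6,6,6,6) for l = 1..4, the standard choice for third-row
# hypervalent pseudoatoms.
.deformation_defaults <- list(
  H  = list(n_l = c(0L, 1L, 2L, 3L, 4L), zeta_au = 2.260),
  C  = list(n_l = c(2L, 2L, 2L, 3L, 4L), zeta_au = 3.176),
  N  = list(n_l = c(2L, 2L, 2L, 3L, 4L), zeta_au = 3.839),
  O  = list(n_l = c(2L, 2L, 2L, 3L, 4L), zeta_au = 4.466),
  F  = list(n_l = c(2L, 2L, 2L, 3L, 4L), zeta_au = 5.108),
  P  = list(n_l = c(6L, 6L, 6L, 6L, 6L), zeta_au = 3.319),
  S  = list(n_l = c(2L, 2L, 4L, 6L, 8L), zeta_au = 3.851),
  Cl = list(n_l = c(4L, 4L, 4L, 4L, 4L), zeta_au = 4.258),
  Br = list(n_l = c(6L, 6L, 6L, 6L, 6L), zeta_au = 4.514)
)

#' Deformation radial model for an element
#'
#' The Slater deformation radial functions `R_l` are parametrized by an
#' integer power `n_l` and an exponent `zeta_l` per multipole order `l`.
#'
#' @param element Element symbol or atomic number.
#' @param n_l Optional integer vector of length 5 (l = 0..4) overriding the
#'   default powers.
#' @param zeta Optional exponent(s) in Angstrom^-1 (length 1 or 5).
#' @return An object of class `radial_model` with fields `n_l` and `zeta`
#'   (both length 5, indexed by l + 1).
#' @export
radial_model <- function(element, n_l = NULL, zeta = NULL) {
  sym <- if (is.numeric(element)) element_symbol(element) else element
  def <- .deformation_defaults[[sym]]
  if (is.null(def) && (is.null(n_l) || is.null(zeta)))
    stop("no default deformation radial model for element: ", sym)
  if (is.null(n_l)) n_l <- def$n_l
  if (is.null(zeta)) zeta <- def$zeta_au / BOHR
  if (length(zeta) == 1L) zeta <- rep(zeta, 5L)
  stopifnot(length(n_l) == 5L, length(zeta) == 5L, all(zeta > 0))
  n_l <- as.integer(n_l)
  if (any(n_l < 0:4)) stop("require n_l >= l for every l (transform ",
                           "convergence)")
  structure(list(element = sym, n_l = n_l, zeta = zeta),
            class = "radial_model")
}
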