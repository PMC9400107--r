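# Least-squares recovery of multipole parameters from (theoretical)
# structure factors.  Complex residuals are fitted directly, which is
# equivalent to constraining phases to the calculated ones for P1
# theoretical targets; weights are unit.

# Build the refinable parameter table for a model.
# Kinds: pval (per atom), kappa / kprime (per constraint group),
# plm (per atom and symmetry-allowed index; hydrogens keep only the
# bond-directed (1,0) and (2,0) functions).
.param_table <- function(model, refinable, atoms = NULL) {
  n <- length(model$sites)
  if (is.null(atoms)) atoms <- seq_len(n)
  rows <- list()
  add <- function(kind, atom, l = NA_integer_, m = NA_integer_,
                  group = NA_integer_, value) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, atom = atom,
                                             l = l, m = m, group = group,
                                             start = value)
  }
  if ("p_val" %in% refinable)
    for (i in atoms) add("pval", i, value = model$sites[[i]]$params$p_val)
  if ("kappa" %in% refinable)
    for (g in unique(model$kappa_groups[atoms])) {
      i <- which(model$kappa_groups == g)[1L]
      add("kappa", i, group = g, value = model$sites[[i]]$params$kappa)
    }
  if ("kappa_prime" %in% refinable)
    for (g in unique(model$kappa_prime_groups[atoms])) {
      i <- which(model$kappa_prime_groups == g)[1L]
      add("kprime", i, group = g,
          value = model$sites[[i]]$params$kappa_prime)
    }
  if ("plm" %in% refinable)
    for (i in atoms) {
      s <- model$sites[[i]]
      ai <- allowed_indices(s$symmetry, s$params$l_max)
      if (model$structure$z[i] == 1L) {
        keep <- (ai[, "l"] == 1L & ai[, "m"] == 0L) |
                (ai[, "l"] == 2L & ai[, "m"] == 0L)
        ai <- ai[keep, , drop = FALSE]
      } else {
        ai <- ai[ai[, "l"] > 0L, , drop = FALSE]
      }
      for (r in seq_len(nrow(ai)))
        add("plm", i, l = ai[r, "l"], m = ai[r, "m"],
            value = plm_get(s$params$plm, ai[r, "l"], ai[r, "m"]))
    }
  if (!length(rows)) stop("empty refinable set")
  do.call(rbind, rows)
}

# Write a parameter vector back into the model.
.apply_params <- function(model, table, par) {
  for (r in seq_len(nrow(table))) {
    kind <- table$kind[r]; v <- par[r]
    if (kind == "pval") {
      model$sites[[table$atom[r]]]$params$p_val <- v
    } else if (kind == "kappa") {
      for (i in which(model$kappa_groups == table$group[r]))
        model$sites[[i]]$params$kappa <- v
    } else if (kind == "kprime") {
      for (i in which(model$kappa_prime_groups == table$group[r]))
        model$sites[[i]]$params$kappa_prime <- v
    } else {
      i <- table$atom[r]
      model$sites[[i]]$params$plm <-
        plm_set(model$sites[[i]]$params$plm, table$l[r], table$m[r], v)
    }
  }
  model
}

# Analytic Jacobian of the complex structure factors wrt the parameters;
# returns a complex matrix n_refl x n_par.
.sf_jacobian <- function(model, refl, pre, table) {
  J <- matrix(0i, nrow(refl$hkl), nrow(table))
  for (r in seq_len(nrow(table))) {
    kind <- table$kind[r]
    if (kind == "pval") {
      i <- table$atom[r]; s <- model$sites[[i]]
      fu <- valence_form_factor(s$sph, refl$H_unique, s$params$kappa)
      J[, r] <- fu[refl$H_idx] * pre[[i]]$phase
    } else if (kind == "kappa") {
      for (i in which(model$kappa_groups == table$group[r])) {
        s <- model$sites[[i]]
        du <- valence_form_factor_dk(s$sph, refl$H_unique, s$params$kappa)
        J[, r] <- J[, r] + s$params$p_val * du[refl$H_idx] * pre[[i]]$phase
      }
    } else if (kind == "kprime") {
      for (i in which(model$kappa_prime_groups == table$group[r])) {
        s <- model$sites[[i]]; p <- s$params
        acc <- complex(real = numeric(nrow(refl$hkl)))
        for (l in 0:p$l_max) {
          pl <- p$plm[l + 1L, (5L - l):(5L + l)]
          if (all(pl == 0)) next
          ang <- drop(pre[[i]]$dvals[[l + 1L]] %*% pl)
          dj <- slater_jl_dkp(l, refl$H_unique, s$radial,
                              p$kappa_prime)[refl$H_idx]
          acc <- acc + (1i)^l * 4 * pi * dj * ang
        }
        J[, r] <- J[, r] + acc * pre[[i]]$phase
      }
    } else {
      i <- table$atom[r]; s <- model$sites[[i]]
      l <- table$l[r]
      dv <- pre[[i]]$dvals[[l + 1L]][, table$m[r] + l + 1L]
      jl <- slater_jl(l, refl$H_unique, s$radial,
                      s$params$kappa_prime)[refl$H_idx]
      J[, r] <- (1i)^l * 4 * pi * jl * dv * pre[[i]]$phase
    }
  }
  J
}

#' Refine multipole parameters against target structure factors
#'
#' Minimizes `sum_h |F_calc(h) - F_target(h)|^2` over the requested
#' parameters by damped least squares with analytic gradients, honoring
#' shared-kappa constraint groups, per-site symmetry selection rules and
#' the hydrogen restriction to bond-directed `(1,0)` / `(2,0)` functions.
#'
#' @param target Complex vector of target structure factors on `refl`.
#' @param model Starting [pseudoatom_model()].
#' @param refl The [generate_reflections()] set the targets live on.
#' @param refinable Subset of
#'   `c("p_val", "kappa", "kappa_prime", "plm")`.
#' @param atoms Restrict refinement to these atom indices (default: all).
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults set
#'   tight tolerances and at most 100 iterations.
#' @return A `refinement_result`: `model` (fitted), `par` (data frame with
#'   start/fit/shift per parameter), `r_factor`
#'   (`sum|dF| / sum|F_target|`), `converged`, `n_iter`, `message`.
#' @export
refine_parameters <- function(target, model, refl,
                              refinable = c("p_val", "kappa", "plm"),
                              atoms = NULL, control = NULL) {
  refinable <- match.arg(refinable,
                         c("p_val", "kappa", "kappa_prime", "plm"),
                         several.ok = TRUE)
  table <- .param_table(model, refinable, atoms)
  pre <- .sf_precompute(model, refl)
  calc <- function(par) {
    m2 <- .apply_params(model, table, par)
    FF <- complex(real = numeric(nrow(refl$hkl)))
    for (i in seq_along(m2$sites))
      FF <- FF + .sf_atom_f(m2, refl, pre, i) * pre[[i]]$phase
    FF
  }
  resid_fn <- function(par) {
    dF <- calc(par) - target
    c(Re(dF), Im(dF))
  }
  jac_fn <- function(par) {
    m2 <- .apply_params(model, table, par)
    J <- .sf_jacobian(m2, refl, pre, table)
    rbind(Re(J), Im(J))
  }
  # rank check on the starting normal equations
  J0 <- jac_fn(table$start)
  qr0 <- qr(J0)
  if (qr0$rank < nrow(table)) {
    null_cols <- qr0$pivot[(qr0$rank + 1L):nrow(table)]
    stop("rank-deficient normal matrix; undetermined parameter(s): ",
         paste(sprintf("%s[atom %d%s]", table$kind[null_cols],
                       table$atom[null_cols],
                       ifelse(is.na(table$l[null_cols]), "",
                              sprintf(" l=%d m=%d", table$l[null_cols],
                                      table$m[null_cols]))),
               collapse = ", "))
  }
  lower <- ifelse(table$kind %in% c("kappa", "kprime"), 0.1, -Inf)
  if (is.null(control))
    control <- minpack.lm::nls.lm.control(maxiter = 100L, ftol = 1e-15,
                                          ptol = 1e-12, gtol = 0)
  fit <- minpack.lm::nls.lm(par = table$start, lower = lower,
                            fn = resid_fn, jac = jac_fn, control = control)
  fitted <- .apply_params(model, table, fit$par)
  dF <- calc(fit$par) - target
  r_factor <- sum(Mod(dF)) / sum(Mod(target))
  par_df <- cbind(table, fit = fit$par, shift = fit$par - table$start)
  structure(list(model = fitted, par = par_df, r_factor = r_factor,
                 converged = fit$info %in% 1:4, n_iter = fit$niter,
                 message = fit$message),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("<refinement_result> ", nrow(x$par), " parameters, R = ",
      format(x$r_factor, digits = 4), ", ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}
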