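# RuBP allosteric activation of carboxysomal carbonic anhydrase and the
# CA hydration/dehydration rate laws.
#
# Unit convention (used throughout the package): concentrations in mM,
# time in seconds. k1 is then s^-1 and k2 mM^-1 s^-1, so the equilibrium
# ratio k1/k2 = 5e-4 mM reproduces the physiological CO2/HCO3- pKa of
# about 6.3 -- the consistency check that pins the convention down.

#' Hill activation parameters for RuBP-dependent CA
#'
#' Bundles the half-maximal activator concentration and Hill slope of the
#' sigmoidal function by which RuBP (its tetra-anionic form, RuBP^4-)
#' switches carboxysomal carbonic anhydrase on. The defaults are the
#' wild-type activation parameters used by the carboxysome model:
#' half-maximal activation at 18 uM RuBP with Hill slope 2.214.
#'
#' @param k_half_uM Activator concentration (uM) giving half-maximal
#'   activation. Must be positive.
#' @param h Dimensionless Hill slope. Must be positive; values above 1
#'   indicate cooperative (allosteric) activation.
#'
#' @return An object of class `hill_activation`.
#' @examples
#' hill <- hill_activation()
#' rubp_activation_factor(0.018, hill) # exactly 0.5 at K_half
#' @export
hill_activation <- function(k_half_uM = 18, h = 2.214) {
  if (!is.numeric(k_half_uM) || length(k_half_uM) != 1L || !is.finite(k_half_uM) ||
      k_half_uM <= 0) {
    abort("`k_half_uM` must be a single positive number.")
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    abort("`h` must be a single positive number.")
  }
  structure(list(k_half_uM = k_half_uM, h = h), class = "hill_activation")
}

#' @export
print.hill_activation <- function(x, ...) {
  cat(sprintf("<hill_activation> K_half = %g uM, h = %g\n", x$k_half_uM, x$h))
  invisible(x)
}

#' RuBP activation factor of carboxysomal CA
#'
#' Evaluates the dimensionless Hill modulation
#' \deqn{f([RuBP]) = \frac{[RuBP]^h}{K_{half}^h + [RuBP]^h}}
#' that scales both the forward (hydration) and backward (dehydration)
#' CA rate constants. The factor is 0 at zero RuBP, exactly 1/2 at
#' `K_half`, and approaches (but never reaches) 1.
#'
#' @param rubp_mM RuBP^4- concentration in mM (vectorised, nonnegative).
#' @param hill A [hill_activation()] object.
#'
#' @return Numeric vector of activation factors in `[0, 1)`.
#' @examples
#' rubp_activation_factor(c(0, 0.018, 0.1), hill_activation())
#' @export
rubp_activation_factor <- function(rubp_mM, hill = hill_activation()) {
  stopifnot(inherits(hill, "hill_activation"))
  if (!is.numeric(rubp_mM) || any(!is.finite(rubp_mM)) || any(rubp_mM < 0)) {
    abort("`rubp_mM` must be finite and nonnegative.")
  }
  k_mM <- hill$k_half_uM / 1000
  # compute via the ratio (x/k)^h for numerical symmetry around K_half
  r <- (rubp_mM / k_mM)^hill$h
  out <- r / (1 + r)
  out[rubp_mM == 0] <- 0
  out
}

#' CA kinetic parameters
#'
#' Rate coefficients of the CO2 <-> HCO3- + H+ interconversion and the
#' catalytic enhancement applied inside a compartment. `ca_factor = 1`
#' denotes the uncatalysed background interconversion (external and
#' unstirred compartments); the carboxysomal CA uses `ca_factor = 1e5`.
#' When `regulated` is `TRUE` both rate constants are additionally
#' multiplied by [rubp_activation_factor()] evaluated at the local
#' RuBP^4- concentration.
#'
#' @param k1 Baseline hydration rate coefficient (s^-1); default 0.05.
#' @param k2 Baseline dehydration rate coefficient (mM^-1 s^-1); default 100.
#' @param ca_factor Dimensionless catalytic enhancement (>= 0 allowed only
#'   as exactly positive; default 1).
#' @param regulated Logical; apply the RuBP Hill modulation?
#' @param hill A [hill_activation()] object; required when `regulated`.
#'
#' @return An object of class `ca_kinetics`.
#' @export
ca_kinetics <- function(k1 = 0.05, k2 = 100, ca_factor = 1,
                        regulated = FALSE, hill = NULL) {
  for (nm in c("k1", "k2", "ca_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  if (isTRUE(regulated)) {
    if (is.null(hill)) hill <- hill_activation()
    stopifnot(inherits(hill, "hill_activation"))
  } else {
    hill <- NULL
  }
  structure(
    list(k1 = k1, k2 = k2, ca_factor = ca_factor,
         regulated = isTRUE(regulated), hill = hill),
    class = "ca_kinetics"
  )
}

#' @export
print.ca_kinetics <- function(x, ...) {
  cat(sprintf(
    "<ca_kinetics> k1 = %g /s, k2 = %g /mM/s, CA factor = %g, %s\n",
    x$k1, x$k2, x$ca_factor,
    if (x$regulated) sprintf("RuBP-regulated (K_half %g uM, h %g)",
                             x$hill$k_half_uM, x$hill$h)
    else "constitutive"
  ))
  invisible(x)
}

.modulation <- function(params, rubp_mM) {
  if (params$regulated) rubp_activation_factor(rubp_mM, params$hill) else 1
}

#' CA hydration rate (CO2 + H2O -> HCO3- + H+)
#'
#' `ca_factor * k1 * [CO2]`, times the RuBP activation factor when the
#' kinetics are regulated. Linear in CO2.
#'
#' @param co2_mM CO2 concentration (mM, nonnegative).
#' @param params A [ca_kinetics()] object.
#' @param rubp_mM RuBP^4- concentration (mM); only used when regulated.
#' @return Flux in mM/s.
#' @export
ca_hydration_rate <- function(co2_mM, params = ca_kinetics(), rubp_mM = 0) {
  stopifnot(inherits(params, "ca_kinetics"))
  if (any(!is.finite(co2_mM)) || any(co2_mM < 0)) {
    abort("`co2_mM` must be finite and nonnegative.")
  }
  params$ca_factor * params$k1 * co2_mM * .modulation(params, rubp_mM)
}

#' CA dehydration rate (HCO3- + H+ -> CO2 + H2O)
#'
#' `ca_factor * k2 * [HCO3-] * [H+]`, times the RuBP activation factor
#' when regulated. Bilinear in bicarbonate and protons. Because hydration
#' and dehydration carry the same `ca_factor` and modulation factor,
#' catalysis and regulation never shift the equilibrium ratio k1/k2.
#'
#' @param hco3_mM Bicarbonate concentration (mM, nonnegative).
#' @param h_mM Proton concentration (mM, nonnegative).
#' @inheritParams ca_hydration_rate
#' @return Flux in mM/s.
#' @export
ca_dehydration_rate <- function(hco3_mM, h_mM, params = ca_kinetics(),
                                rubp_mM = 0) {
  stopifnot(inherits(params, "ca_kinetics"))
  if (any(!is.finite(hco3_mM)) || any(hco3_mM < 0) ||
      any(!is.finite(h_mM)) || any(h_mM < 0)) {
    abort("`hco3_mM` and `h_mM` must be finite and nonnegative.")
  }
  params$ca_factor * params$k2 * hco3_mM * h_mM * .modulation(params, rubp_mM)
}
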