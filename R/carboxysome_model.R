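# Three-compartment reaction-diffusion model of a single alpha-carboxysome:
# a clamped external reservoir, an unstirred boundary layer, and the
# carboxysome lumen holding Rubisco and the (optionally RuBP-regulated) CA.
# Species: CO2, HCO3-, H+, O2, RuBP; concentrations in mM, time in s.

.SPECIES <- c("co2", "hco3", "h", "o2", "rubp")

#' Rubisco kinetic parameters
#'
#' Form-I Rubisco catalytic constants with competitive O2 inhibition at the
#' CO2 site and independent RuBP Michaelis saturation. Defaults are the
#' Cyanobium values used by the carboxysome model: kcatC = 9.4 /s,
#' KM(CO2) = 169 uM, KM(O2) = 1.4 mM, kcatO = 1.42 /s, KM(RuBP) = 40 uM,
#' and an active-site concentration of 5.68 mM
#' (see [rubisco_site_concentration()]).
#'
#' @param kcat_c Carboxylation turnover (s^-1).
#' @param km_co2_uM Michaelis constant for CO2 (uM).
#' @param km_o2_mM Michaelis constant for O2 (mM).
#' @param kcat_o Oxygenation turnover (s^-1).
#' @param km_rubp_uM Michaelis constant for RuBP (uM).
#' @param e_sites_mM Active-site concentration in the carboxysome (mM).
#' @return An object of class `rubisco_params`.
#' @export
rubisco_params <- function(kcat_c = 9.4, km_co2_uM = 169, km_o2_mM = 1.4,
                           kcat_o = 1.42, km_rubp_uM = 40,
                           e_sites_mM = 5.68) {
  vals <- c(kcat_c = kcat_c, km_co2_uM = km_co2_uM, km_o2_mM = km_o2_mM,
            kcat_o = kcat_o, km_rubp_uM = km_rubp_uM, e_sites_mM = e_sites_mM)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All Rubisco parameters must be positive and finite.")
  }
  structure(as.list(vals), class = "rubisco_params")
}

#' Rubisco active-site concentration from carboxysome geometry
#'
#' Converts a count of Rubisco holoenzymes packed into a spherical
#' carboxysome into a molar active-site concentration. The default
#' geometry -- 224 L8S8 holoenzymes (8 catalytic sites each) in a 100 nm
#' diameter sphere -- gives 5.68 mM.
#'
#' @param n_holoenzymes Number of holoenzymes in the carboxysome.
#' @param sites_per_holoenzyme Catalytic sites per holoenzyme (8 for L8S8).
#' @param diameter_nm Carboxysome diameter in nm.
#' @return Active-site concentration in mM.
#' @examples
#' rubisco_site_concentration(224, 8, 100)
#' @export
rubisco_site_concentration <- function(n_holoenzymes = 224,
                                       sites_per_holoenzyme = 8,
                                       diameter_nm = 100) {
  if (n_holoenzymes < 0 || sites_per_holoenzyme <= 0 || diameter_nm <= 0) {
    abort("Geometry arguments must be positive (holoenzyme count may be 0).")
  }
  avogadro <- 6.02214076e23
  vol_L <- sphere_volume_L(diameter_nm)
  mol <- n_holoenzymes * sites_per_holoenzyme / avogadro
  mol / vol_L * 1000 # mol/L -> mM
}

# volume of a sphere of given diameter (nm), in liters
sphere_volume_L <- function(diameter_nm) {
  r_m <- diameter_nm / 2 * 1e-9
  (4 / 3) * pi * r_m^3 * 1000
}

#' Rubisco carboxylation rate
#'
#' \deqn{v_c = k_{catC} E \frac{[CO_2]}{K_{M,CO_2}(1 + [O_2]/K_{M,O_2}) +
#' [CO_2]} \cdot \frac{[RuBP]}{K_{M,RuBP} + [RuBP]}}
#' with competitive O2 inhibition at the CO2 site; bounded above by
#' `kcat_c * E`.
#'
#' @param state Named numeric vector or list with elements `co2`, `o2`,
#'   `rubp` (mM).
#' @param p A [rubisco_params()] object.
#' @return Flux in mM/s.
#' @export
rubisco_carboxylation_rate <- function(state, p = rubisco_params()) {
  stopifnot(inherits(p, "rubisco_params"))
  co2 <- state[["co2"]]; o2 <- state[["o2"]]; rubp <- state[["rubp"]]
  km_co2 <- p$km_co2_uM / 1000
  km_rubp <- p$km_rubp_uM / 1000
  sat_c <- co2 / (km_co2 * (1 + o2 / p$km_o2_mM) + co2)
  sat_r <- rubp / (km_rubp + rubp)
  if (co2 == 0) sat_c <- 0
  if (rubp == 0) sat_r <- 0
  p$kcat_c * p$e_sites_mM * sat_c * sat_r
}

#' Rubisco oxygenation rate
#'
#' Mirror image of [rubisco_carboxylation_rate()] with the CO2/O2 roles
#' swapped: O2 saturates its own site with competitive CO2 inhibition,
#' times the same RuBP Michaelis saturation.
#'
#' @inheritParams rubisco_carboxylation_rate
#' @return Flux in mM/s.
#' @export
rubisco_oxygenation_rate <- function(state, p = rubisco_params()) {
  stopifnot(inherits(p, "rubisco_params"))
  co2 <- state[["co2"]]; o2 <- state[["o2"]]; rubp <- state[["rubp"]]
  km_co2 <- p$km_co2_uM / 1000
  km_rubp <- p$km_rubp_uM / 1000
  sat_o <- o2 / (p$km_o2_mM * (1 + co2 / km_co2) + o2)
  sat_r <- rubp / (km_rubp + rubp)
  if (o2 == 0) sat_o <- 0
  if (rubp == 0) sat_r <- 0
  p$kcat_o * p$e_sites_mM * sat_o * sat_r
}

#' First-order transmembrane transport flux
#'
#' Exchange flux of one species across an interface, first-order in the
#' concentration difference and referenced to the receiving compartment's
#' volume: `k[species] * (donor - receiver)` in mM/s of the receiver.
#'
#' @param species One of `"co2"`, `"hco3"`, `"h"`, `"o2"`, `"rubp"`.
#' @param donor_mM,receiver_mM Concentrations on either side (mM).
#' @param transport Named vector of exchange coefficients (s^-1), one per
#'   species.
#' @return Flux into the receiver, mM/s.
#' @export
transport_flux <- function(species, donor_mM, receiver_mM, transport) {
  if (!species %in% names(transport)) {
    abort(sprintf("No transport coefficient configured for species '%s'.",
                  species))
  }
  if (any(transport < 0)) abort("Transport coefficients must be nonnegative.")
  transport[[species]] * (donor_mM - receiver_mM)
}

#' Fraction of RuBP in the tetra-anionic (RuBP^4-) form
#'
#' Single effective-ionisation Henderson--Hasselbalch speciation:
#' `fraction = 1 / (1 + 10^(pKa - pH))`. Mode `"full"` treats all RuBP as
#' fully deprotonated (fraction 1) regardless of pH.
#'
#' @param total_rubp_mM Total RuBP concentration (mM, nonnegative).
#' @param pH Compartment pH.
#' @param pka_eff Effective pKa of the final ionisation (default 6.7).
#' @param mode `"pka"` (default) or `"full"`.
#' @return RuBP^4- concentration in mM.
#' @export
rubp_speciation <- function(total_rubp_mM, pH, pka_eff = 6.7,
                            mode = c("pka", "full")) {
  mode <- match.arg(mode)
  if (any(total_rubp_mM < 0)) abort("`total_rubp_mM` must be nonnegative.")
  if (mode == "full") return(total_rubp_mM)
  total_rubp_mM / (1 + 10^(pka_eff - pH))
}

#' pH from proton concentration in mM
#'
#' `-log10([H+] in M)`; with `[H+]` supplied in mM this is
#' `3 - log10([H+] mM)`.
#'
#' @param h_mM Proton concentration in mM (positive).
#' @return pH value(s).
#' @examples
#' carboxysome_pH(1e-5) # 8
#' @export
carboxysome_pH <- function(h_mM) {
  if (any(!is.finite(h_mM)) || any(h_mM <= 0)) {
    abort("`h_mM` must be positive to compute a pH.")
  }
  -log10(h_mM / 1000)
}

#' Assemble a carboxysome reaction-diffusion model
#'
#' Builds the full parameter set for the three-compartment model:
#' a clamped external reservoir (default 20 mM HCO3-, pH 8.0, 0.25 mM O2 --
#' air-equilibrated water -- 10 uM free CO2 held out of equilibrium by the
#' cell, and a swept RuBP level), an unstirred boundary layer, and the
#' carboxysome lumen. CA activity is confined to the lumen
#' (`ca_factor = 1e5`, optionally RuBP-regulated); the unstirred layer
#' carries only background interconversion (`ca_factor = 1`), never
#' regulated. Carboxylation consumes one CO2 and one RuBP and releases
#' `n_h_carboxylation` protons; oxygenation consumes one RuBP. Reaction
#' products (3-PGA, 2-phosphoglycolate) are treated as sinks.
#'
#' @param regulated Logical; is the carboxysomal CA RuBP-dependent?
#' @param hill [hill_activation()] parameters of the regulation.
#' @param ca_carboxysome [ca_kinetics()] for the lumen. Overrides
#'   `regulated`/`hill` if supplied.
#' @param ca_unstirred [ca_kinetics()] for the unstirred layer (background
#'   interconversion; must not be regulated).
#' @param rubisco [rubisco_params()], or `NULL` for a Rubisco-free model.
#' @param external Named vector of clamped external concentrations (mM)
#'   for `co2`, `hco3`, `h`, `o2`, `rubp`.
#' @param diameter_nm Carboxysome diameter (nm).
#' @param unstirred_volume_ratio Unstirred-layer volume as a multiple of
#'   the carboxysome volume.
#' @param transport_ext Exchange coefficients (s^-1, referenced to the
#'   unstirred layer) across the external/unstirred interface.
#' @param transport_shell Exchange coefficients (s^-1, referenced to the
#'   lumen) across the shell.
#' @param n_h_carboxylation Protons released per carboxylation (0--2;
#'   default 2, the stoichiometry of RuBP^4- + CO2 -> 2 PGA^3- + 2 H+ at
#'   carboxysomal pH). These protons drive net CA dehydration and hence
#'   luminal CO2 elevation.
#' @param pka_rubp Effective pKa for RuBP^4- speciation.
#' @param speciation `"pka"` or `"full"` (see [rubp_speciation()]).
#' @param clamp_rubp Logical; clamp luminal RuBP at the external level
#'   instead of letting transport and consumption set it.
#'
#' @return An object of class `carboxysome_model`.
#' @examples
#' m <- carboxysome_model(regulated = TRUE)
#' ss <- solve_steady_state(m)
#' carboxysome_pH(ss[["h_c"]])
#' @export
carboxysome_model <- function(regulated = FALSE,
                              hill = hill_activation(),
                              ca_carboxysome = NULL,
                              ca_unstirred = ca_kinetics(ca_factor = 1),
                              rubisco = rubisco_params(),
                              external = c(co2 = 0.01, hco3 = 20, h = 1e-5,
                                           o2 = 0.25, rubp = 0.001),
                              diameter_nm = 100,
                              unstirred_volume_ratio = 10,
                              transport_ext = c(co2 = 1000, hco3 = 1000,
                                                h = 1000, o2 = 1000,
                                                rubp = 1000),
                              transport_shell = c(co2 = 100, hco3 = 100,
                                                  h = 1000, o2 = 100,
                                                  rubp = 10),
                              n_h_carboxylation = 2,
                              pka_rubp = 6.7,
                              speciation = c("pka", "full"),
                              clamp_rubp = FALSE) {
  speciation <- match.arg(speciation)
  if (is.null(ca_carboxysome)) {
    ca_carboxysome <- ca_kinetics(ca_factor = 1e5, regulated = regulated,
                                  hill = hill)
  }
  stopifnot(inherits(ca_carboxysome, "ca_kinetics"),
            inherits(ca_unstirred, "ca_kinetics"))
  if (ca_unstirred$regulated) {
    abort("The unstirred-layer background interconversion is never RuBP-regulated.")
  }
  if (!is.null(rubisco)) stopifnot(inherits(rubisco, "rubisco_params"))
  ext <- external[.SPECIES]
  if (any(is.na(ext)) || any(ext < 0)) {
    abort("`external` must name nonnegative co2, hco3, h, o2 and rubp (mM).")
  }
  for (tp in list(transport_ext, transport_shell)) {
    if (any(is.na(tp[.SPECIES])) || any(tp < 0)) {
      abort("Transport coefficients must be nonnegative for all five species.")
    }
  }
  if (diameter_nm <= 0 || unstirred_volume_ratio <= 0) {
    abort("Geometry parameters must be positive.")
  }
  if (n_h_carboxylation < 0 || n_h_carboxylation > 2) {
    abort("`n_h_carboxylation` must lie in [0, 2].")
  }
  structure(list(
    ca_carboxysome = ca_carboxysome,
    ca_unstirred = ca_unstirred,
    rubisco = rubisco,
    external = ext,
    diameter_nm = diameter_nm,
    unstirred_volume_ratio = unstirred_volume_ratio,
    transport_ext = transport_ext[.SPECIES],
    transport_shell = transport_shell[.SPECIES],
    n_h_carboxylation = n_h_carboxylation,
    pka_rubp = pka_rubp,
    speciation = speciation,
    clamp_rubp = isTRUE(clamp_rubp)
  ), class = "carboxysome_model")
}

#' @export
print.carboxysome_model <- function(x, ...) {
  cat("<carboxysome_model>\n")
  cat(sprintf("  lumen CA: factor %g, %s\n", x$ca_carboxysome$ca_factor,
              if (x$ca_carboxysome$regulated) "RuBP-regulated" else "constitutive"))
  cat(sprintf("  Rubisco: %s\n",
              if (is.null(x$rubisco)) "absent"
              else sprintf("%g mM sites, kcatC %g /s", x$rubisco$e_sites_mM,
                           x$rubisco$kcat_c)))
  cat(sprintf("  external: HCO3- %g mM, pH %.2f, O2 %g mM, RuBP %g mM\n",
              x$external[["hco3"]], carboxysome_pH(x$external[["h"]]),
              x$external[["o2"]], x$external[["rubp"]]))
  invisible(x)
}

# state vector layout: <species>_u then <species>_c
.state_names <- function() c(paste0(.SPECIES, "_u"), paste0(.SPECIES, "_c"))

.default_init <- function(model) {
  ext <- model$external
  setNames(c(ext, ext), .state_names())
}

#' Time derivatives of the carboxysome model state
#'
#' Sums transport and reaction terms for every dynamic species: CA
#' hydration consumes CO2 and produces HCO3- + H+ (dehydration the
#' reverse); carboxylation consumes 1 CO2 + 1 RuBP and releases
#' `n_h_carboxylation` protons; oxygenation consumes 1 RuBP. Transport
#' fluxes conserve mass across interfaces (volume-ratio corrected).
#'
#' @param state Named numeric vector over `co2_u ... rubp_u,
#'   co2_c ... rubp_c` (mM); see [solve_steady_state()].
#' @param model A [carboxysome_model()].
#' @return Named numeric vector of d(state)/dt in mM/s.
#' @export
carboxysome_derivatives <- function(state, model) {
  if (any(state < 0)) abort("State concentrations must be nonnegative.")
  .deriv(state, model)
}

.deriv <- function(state, model) {
  u <- state[1:5]; cc <- state[6:10]
  names(u) <- names(cc) <- .SPECIES
  ext <- model$external
  r_vol <- 1 / model$unstirred_volume_ratio # v_cbx / v_un

  ke <- model$transport_ext
  ks <- model$transport_shell
  flux_in_u <- ke * (ext - u)            # into unstirred, mM/s of unstirred
  flux_in_c <- ks * (u - cc)             # into lumen, mM/s of lumen

  du <- flux_in_u - flux_in_c * r_vol
  dc <- flux_in_c

  # background interconversion in the unstirred layer
  hyd_u <- ca_hydration_rate(u[["co2"]], model$ca_unstirred)
  deh_u <- ca_dehydration_rate(u[["hco3"]], u[["h"]], model$ca_unstirred)
  du[["co2"]] <- du[["co2"]] + deh_u - hyd_u
  du[["hco3"]] <- du[["hco3"]] + hyd_u - deh_u
  du[["h"]] <- du[["h"]] + hyd_u - deh_u

  # carboxysomal CA, modulated by luminal RuBP^4-
  rubp4 <- if (cc[["h"]] > 0) {
    rubp_speciation(cc[["rubp"]], carboxysome_pH(cc[["h"]]),
                    pka_eff = model$pka_rubp, mode = model$speciation)
  } else cc[["rubp"]]
  hyd_c <- ca_hydration_rate(cc[["co2"]], model$ca_carboxysome, rubp4)
  deh_c <- ca_dehydration_rate(cc[["hco3"]], cc[["h"]], model$ca_carboxysome,
                               rubp4)
  dc[["co2"]] <- dc[["co2"]] + deh_c - hyd_c
  dc[["hco3"]] <- dc[["hco3"]] + hyd_c - deh_c
  dc[["h"]] <- dc[["h"]] + hyd_c - deh_c

  if (!is.null(model$rubisco)) {
    vc <- rubisco_carboxylation_rate(cc, model$rubisco)
    vo <- rubisco_oxygenation_rate(cc, model$rubisco)
    dc[["co2"]] <- dc[["co2"]] - vc
    dc[["o2"]] <- dc[["o2"]] - vo
    dc[["rubp"]] <- dc[["rubp"]] - vc - vo
    dc[["h"]] <- dc[["h"]] + model$n_h_carboxylation * vc
  }

  if (model$clamp_rubp) dc[["rubp"]] <- 0

  setNames(c(du, dc), .state_names())
}

# Damped Newton polish on the steady-state equations; minimum-norm step
# (pseudo-inverse) when the Jacobian is rank-deficient, as in closed
# systems with conservation laws.
.newton_polish <- function(x, model, tol, max_iter = 60) {
  f <- .deriv(x, model)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      hstep <- 1e-6 * max(abs(x[j]), 1e-9)
      xp <- x; xp[j] <- x[j] + hstep
      xm <- x; xm[j] <- max(x[j] - hstep, 0)
      J[, j] <- (.deriv(xp, model) - .deriv(xm, model)) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- as.numeric(MASS::ginv(J) %*% f)
    }
    lambda <- 1
    f0 <- max(abs(f))
    repeat {
      xn <- x - lambda * step
      xn <- pmax(xn, 0)
      fn <- .deriv(xn, model)
      if (max(abs(fn)) < f0 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (max(abs(fn)) >= f0) break # no further progress possible
    x <- xn; f <- fn
  }
  list(state = x, residual = max(abs(f)))
}

#' Solve the carboxysome model to steady state
#'
#' Integrates the stiff ODE system to quiescence (deSolve, `lsoda`) and
#' polishes the result with a damped Newton iteration until the
#' infinity-norm of the time derivative falls below `tol` (mM/s). The
#' evaluation order is fixed, so the result is deterministic for fixed
#' inputs.
#'
#' @param model A [carboxysome_model()].
#' @param init Optional named initial state; defaults to both compartments
#'   set to the external concentrations.
#' @param tol Convergence tolerance on `max |d state/dt|` (mM/s).
#' @param t_max Integration horizon (s) per attempt.
#' @return The steady state as a named numeric vector with attribute
#'   `residual`. Errors (with the residual reported) on non-convergence.
#' @export
solve_steady_state <- function(model, init = NULL, tol = 1e-10, t_max = 50) {
  stopifnot(inherits(model, "carboxysome_model"))
  x <- if (is.null(init)) .default_init(model) else init[.state_names()]
  if (any(is.na(x)) || any(x < 0)) abort("`init` must be a full nonnegative state.")
  if (model$clamp_rubp) x[["rubp_c"]] <- model$external[["rubp"]]

  rhs <- function(t, y, parms) list(.deriv(pmax(y, 0), model))
  horizon <- t_max
  for (attempt in 1:3) {
    sol <- deSolve::lsoda(y = x, times = c(0, horizon), func = rhs,
                          rtol = 1e-8, atol = 1e-14, maxsteps = 50000)
    x <- pmax(sol[nrow(sol), -1], 0)
    pol <- .newton_polish(x, model, tol)
    x <- pol$state
    if (pol$residual < tol) {
      out <- setNames(as.numeric(x), .state_names())
      attr(out, "residual") <- pol$residual
      return(out)
    }
    horizon <- horizon * 100
  }
  abort(sprintf(
    "Steady-state solve did not converge: residual %.3e mM/s exceeds tol %.1e.",
    pol$residual, tol))
}

#' Steady-state fluxes of a carboxysome model state
#'
#' Reports the luminal reaction fluxes at a given state: Rubisco
#' carboxylation and oxygenation (mM/s and per-site s^-1), CA hydration,
#' dehydration and net dehydration flux, and the luminal pH.
#'
#' @inheritParams carboxysome_derivatives
#' @return A one-row tibble.
#' @export
carboxysome_fluxes <- function(state, model) {
  cc <- setNames(as.numeric(state[6:10]), .SPECIES)
  rubp4 <- rubp_speciation(cc[["rubp"]], carboxysome_pH(cc[["h"]]),
                           pka_eff = model$pka_rubp, mode = model$speciation)
  hyd <- ca_hydration_rate(cc[["co2"]], model$ca_carboxysome, rubp4)
  deh <- ca_dehydration_rate(cc[["hco3"]], cc[["h"]], model$ca_carboxysome,
                             rubp4)
  if (!is.null(model$rubisco)) {
    vc <- rubisco_carboxylation_rate(cc, model$rubisco)
    vo <- rubisco_oxygenation_rate(cc, model$rubisco)
    e <- model$rubisco$e_sites_mM
  } else {
    vc <- vo <- 0; e <- NA_real_
  }
  tibble::tibble(
    vc_mM_s = vc, vo_mM_s = vo,
    kcat_c_eff_s = vc / e, kcat_o_eff_s = vo / e,
    ca_hydration_mM_s = hyd, ca_dehydration_mM_s = deh,
    ca_flux_mM_s = deh - hyd,
    ph_cbx = carboxysome_pH(cc[["h"]])
  )
}

#' Sweep external RuBP and record steady-state outputs
#'
#' Solves the model to steady state at each external RuBP level (warm
#' starting each level from the previous solution) and returns one tidy
#' row per level: the effective per-site carboxylation and oxygenation
#' turnover, the net CA dehydration flux, the luminal pH, and the full
#' steady state. The default grid is 20 log-spaced levels over
#' 0.1 uM -- 5 mM, the range spanning the CA activation K_M.
#'
#' @param model A [carboxysome_model()].
#' @param rubp_levels_mM Positive, sorted RuBP levels (mM).
#' @param tol Steady-state tolerance, passed to [solve_steady_state()].
#' @return A tibble with one row per level.
#' @export
run_rubp_sweep <- function(model,
                           rubp_levels_mM = rubp_sweep_grid(),
                           tol = 1e-10) {
  stopifnot(inherits(model, "carboxysome_model"))
  if (any(rubp_levels_mM <= 0)) abort("RuBP levels must be positive.")
  if (is.unsorted(rubp_levels_mM)) abort("RuBP levels must be sorted increasing.")
  init <- NULL
  rows <- vector("list", length(rubp_levels_mM))
  for (i in seq_along(rubp_levels_mM)) {
    lev <- rubp_levels_mM[i]
    m <- model
    m$external[["rubp"]] <- lev
    ss <- tryCatch(
      solve_steady_state(m, init = init, tol = tol),
      error = function(e) {
        abort(sprintf("Sweep failed at RuBP = %g mM: %s", lev,
                      conditionMessage(e)))
      })
    init <- ss
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(rubp_mM = lev),
      carboxysome_fluxes(ss, m),
      tibble::as_tibble(as.list(ss))
    )
  }
  dplyr::bind_rows(rows)
}

#' Default RuBP sweep grid
#'
#' Log-spaced external RuBP levels over 0.1 uM -- 5 mM.
#'
#' @param n Number of levels.
#' @return Numeric vector of concentrations in mM.
#' @export
rubp_sweep_grid <- function(n = 20) {
  10^seq(log10(1e-4), log10(5), length.out = n)
}
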