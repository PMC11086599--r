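# Seeded generators for every input the analysis consumes: three-segment
# MIMS isotopologue washout traces and effector dose-response curves.
# In the zero-noise limit every analysis operation recovers the generator
# truth exactly (generator/analyzer adjointness), which the test suite
# exploits throughout.

#' Piecewise-exponential enrichment decay
#'
#' Closed-form 18O enrichment at time `t` for an assay whose first-order
#' washout rate changes at each reagent addition: continuous, piecewise
#' exponential with per-segment rates.
#'
#' @param t Time (minutes, vectorised).
#' @param rates Segment rates (per minute), in chronological order
#'   (`pre_protein`, `post_protein`, and optionally `post_effector`).
#' @param event_times Times of the rate changes (minutes), length
#'   `length(rates) - 1`, increasing.
#' @param init_enrichment Enrichment at `t = 0` (in `(0, 1]`).
#' @return Enrichment fraction at each `t`.
#' @export
piecewise_enrichment <- function(t, rates, event_times,
                                 init_enrichment = 0.8) {
  if (length(event_times) != length(rates) - 1) {
    abort("`event_times` must have one fewer element than `rates`.")
  }
  if (any(rates < 0)) abort("Rates must be nonnegative.")
  if (init_enrichment <= 0 || init_enrichment > 1) {
    abort("`init_enrichment` must lie in (0, 1].")
  }
  breaks <- c(0, event_times, Inf)
  decay <- numeric(length(t))
  for (i in seq_along(rates)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    decay <- decay + rates[i] * pmax(pmin(t, hi) - lo, 0)
  }
  init_enrichment * exp(-decay)
}

#' Simulate a MIMS isotopologue washout trace
#'
#' Generates the six CO2 isotopologue channels of an 18O-exchange assay in
#' which the enrichment declines as a piecewise exponential: a slow
#' uncatalysed background phase, a faster phase after enzyme addition and
#' (optionally) a further change after effector addition. Channel
#' intensities realise the target enrichment exactly in expectation by
#' allocating each molecule's two oxygens independently (18O count
#' binomial in the enrichment), split between 12C and 13C channels by
#' `frac_13c`; multiplicative log-normal noise is applied per channel.
#' Output is exactly reproducible per seed.
#'
#' @param rates Named or ordered segment rates (per minute):
#'   pre-protein, post-protein, and optionally post-effector.
#' @param event_times Addition times (minutes), one fewer than rates;
#'   named `protein` (and `effector`) in the returned trace.
#' @param t_end Trace length (minutes).
#' @param dt Sampling interval (minutes).
#' @param init_enrichment Starting 18O enrichment fraction.
#' @param scale Total channel intensity (arbitrary units).
#' @param noise_sd Log-normal sigma of the per-channel multiplicative
#'   noise (~ relative sd); 0 for noiseless.
#' @param frac_13c Fraction of the CO2 pool carrying 13C (labelled
#'   source; default 0.95).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [mims_trace()].
#' @examples
#' tr <- simulate_mims_trace(seed = 42)
#' segment_rates(tr)
#' @export
simulate_mims_trace <- function(rates = c(pre_protein = 0.01,
                                          post_protein = 0.5,
                                          post_effector = 0.5),
                                event_times = c(protein = 5, effector = 10),
                                t_end = 15, dt = 0.05,
                                init_enrichment = 0.8,
                                scale = 1e5, noise_sd = 0.01,
                                frac_13c = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (frac_13c < 0 || frac_13c > 1) abort("`frac_13c` must lie in [0, 1].")
  t <- seq(0, t_end, by = dt)
  enr <- piecewise_enrichment(t, rates, unname(event_times), init_enrichment)
  # binomial allocation of two oxygens per molecule
  p0 <- (1 - enr)^2; p1 <- 2 * enr * (1 - enr); p2 <- enr^2
  means <- cbind(
    mz44 = scale * (1 - frac_13c) * p0, mz45 = scale * frac_13c * p0,
    mz46 = scale * (1 - frac_13c) * p1, mz47 = scale * frac_13c * p1,
    mz48 = scale * (1 - frac_13c) * p2, mz49 = scale * frac_13c * p2
  )
  if (noise_sd > 0) {
    noise <- matrix(exp(rnorm(length(means), 0, noise_sd)),
                    nrow = nrow(means))
    means <- means * noise
  }
  ev <- unname(event_times)
  names(ev) <- if (length(ev) == 2) c("protein", "effector") else "protein"
  mims_trace(tibble::as_tibble(cbind(time_min = t, means)), events = ev)
}

#' Generate a synthetic dose-response curve
#'
#' Evaluates a truth model (Hill, Michaelis-Menten or biphasic) on a
#' concentration grid and adds replicated additive Gaussian noise with
#' standard deviation `noise_sd * v_max` (full-scale relative, so
#' zero-activity points are as noisy as saturated ones, as in a real rate
#' assay). Seeded and exactly reproducible.
#'
#' @param model `"hill"`, `"michaelis_menten"` or `"biphasic"`.
#' @param v_max Maximal rate (arbitrary units).
#' @param k_half_uM Half-saturation constant (uM).
#' @param h Hill slope (ignored for `michaelis_menten`).
#' @param basal Basal rate (biphasic only).
#' @param conc_uM Concentration grid (uM); default 12 log-spaced points
#'   over 0.1--1000 uM.
#' @param replicates Technical replicates per concentration.
#' @param noise_sd Noise sd as a fraction of `v_max`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with columns `effector_uM`, `replicate`, `rate`, and
#'   the truth parameters in attribute `"truth"`.
#' @export
generate_response_curve <- function(model = c("hill", "michaelis_menten",
                                              "biphasic"),
                                    v_max = 1, k_half_uM = 18, h = 2.214,
                                    basal = 0,
                                    conc_uM = 10^seq(log10(0.1), log10(1000),
                                                     length.out = 12),
                                    replicates = 3, noise_sd = 0.02,
                                    seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (v_max <= 0 || k_half_uM <= 0 || h <= 0 || basal < 0 || noise_sd < 0) {
    abort("Generator parameters must be positive (basal and noise_sd may be 0).")
  }
  truth <- switch(model,
    hill = .hill_fun(conc_uM, v_max, k_half_uM, h),
    michaelis_menten = .hill_fun(conc_uM, v_max, k_half_uM, 1),
    biphasic = .biphasic_fun(conc_uM, v_max, k_half_uM, h, basal))
  out <- tidyr::expand_grid(replicate = seq_len(replicates),
                            effector_uM = conc_uM)
  out$rate <- rep(truth, times = replicates) +
    rnorm(nrow(out), 0, noise_sd * v_max)
  out <- dplyr::select(out, "effector_uM", "replicate", "rate")
  attr(out, "truth") <- list(model = model, v_max = v_max,
                             k_half_uM = k_half_uM,
                             h = if (model == "michaelis_menten") 1 else h,
                             basal = if (model == "biphasic") basal else 0)
  out
}

#' Generate a panel of qualitatively distinct enzyme variants
#'
#' Synthetic dose-response curves for the four behaviour classes seen
#' across carboxysomal CA variants: a wild-type-like sigmoidal activator
#' response, a constitutive enzyme (high effector-independent activity,
#' no meaningful further activation), a biphasic variant (substantial
#' basal activity plus an effector-dependent increase) and a dead enzyme.
#' Truth parameters for each class are attached to each curve as the
#' `"truth"` attribute.
#'
#' @param seed Integer seed.
#' @param noise_sd Noise sd as a fraction of the wild-type `v_max`.
#' @return Named list of tibbles: `wild_type`, `constitutive`,
#'   `biphasic`, `dead`.
#' @export
generate_mutant_panel <- function(seed = 1, noise_sd = 0.02) {
  specs <- list(
    wild_type = list(model = "hill", v_max = 1, k_half_uM = 18, h = 2.214,
                     basal = 0),
    constitutive = list(model = "biphasic", v_max = 1, k_half_uM = 18,
                        h = 2.214, basal = 0.95),
    biphasic = list(model = "biphasic", v_max = 1, k_half_uM = 18,
                    h = 2.214, basal = 0.6),
    dead = list(model = "hill", v_max = 0.02, k_half_uM = 18, h = 2.214,
                basal = 0)
  )
  purrr::imap(specs, function(s, nm) {
    generate_response_curve(
      model = s$model, v_max = s$v_max, k_half_uM = s$k_half_uM, h = s$h,
      basal = s$basal, noise_sd = noise_sd / s$v_max,
      seed = seed + match(nm, names(specs)))
  })
}
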