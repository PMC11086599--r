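# 18O-exchange CA activity from membrane inlet mass spectrometry (MIMS)
# CO2 isotopologue traces. The assay follows the loss of 18O from a
# 13C-labelled, 18O-enriched bicarbonate pool into water through the
# CA-catalysed CO2/HCO3- interconversion: the first-order decline rate of
# the 18O atom-fraction enrichment of measured CO2 reports CA activity.

# channel -> number of 18O atoms; m/z 44/46/48 are 12C with 0/1/2 18O,
# 45/47/49 the 13C counterparts. Only these six channels are summed.
.MZ_CHANNELS <- c(mz44 = 0, mz45 = 0, mz46 = 1, mz47 = 1, mz48 = 2, mz49 = 2)

#' Construct a MIMS trace
#'
#' Bundles a CO2 isotopologue time series with the reagent-addition event
#' times that segment the assay (protein addition, effector addition).
#'
#' @param data Data frame with columns `time_min` (strictly increasing)
#'   and the six channel intensities `mz44`--`mz49` (arbitrary units,
#'   nonnegative).
#' @param events Named numeric vector of event times (minutes) within the
#'   time range; typically `c(protein = ..., effector = ...)`.
#' @return An object of class `mims_trace` (list with elements `data` and
#'   `events`).
#' @export
mims_trace <- function(data, events = numeric()) {
  data <- tibble::as_tibble(data)
  need <- c("time_min", names(.MZ_CHANNELS))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(data$time_min, strictly = TRUE)) {
    abort("`time_min` must be strictly increasing.")
  }
  ab <- as.matrix(data[names(.MZ_CHANNELS)])
  if (any(ab < 0)) abort("Channel abundances must be nonnegative.")
  if (length(events) > 0) {
    if (is.null(names(events)) || any(names(events) == "")) {
      abort("`events` must be a named numeric vector of times (minutes).")
    }
    rng <- range(data$time_min)
    if (any(events < rng[1] | events > rng[2])) {
      abort("Event times must lie within the trace time range.")
    }
  }
  structure(list(data = data, events = events), class = "mims_trace")
}

#' @export
print.mims_trace <- function(x, ...) {
  cat(sprintf("<mims_trace> %d points, %.2f--%.2f min\n",
              nrow(x$data), min(x$data$time_min), max(x$data$time_min)))
  if (length(x$events) > 0) {
    cat("  events:", paste(sprintf("%s @ %.2f min", names(x$events),
                                   x$events), collapse = ", "), "\n")
  }
  invisible(x)
}

#' 18O atom-fraction enrichment of measured CO2
#'
#' At each time point sums the related carbon species over the six
#' isotopologue channels:
#' \deqn{E = \frac{\sum_i a_i \, n_i^{18O}}{2 \sum_i a_i}}
#' where \eqn{n_i^{18O}} is the number of 18O atoms carried by channel
#' \eqn{i} (m/z 44/45: 0; 46/47: 1; 48/49: 2). The statistic is intensive:
#' rescaling all channels at a point by any positive constant leaves it
#' unchanged.
#'
#' @param trace A [mims_trace()] or a data frame with `time_min` and
#'   `mz44`--`mz49` columns.
#' @return A tibble with columns `time_min` and `enrichment` (in `[0, 1]`).
#' @export
atom_fraction_enrichment <- function(trace) {
  df <- if (inherits(trace, "mims_trace")) trace$data else
    mims_trace(trace)$data
  ab <- as.matrix(df[names(.MZ_CHANNELS)])
  tot <- rowSums(ab)
  if (any(tot == 0)) {
    abort(sprintf("Enrichment undefined: all channels zero at t = %g min.",
                  df$time_min[which(tot == 0)[1]]))
  }
  enr <- as.numeric(ab %*% .MZ_CHANNELS) / (2 * tot)
  tibble::tibble(time_min = df$time_min, enrichment = enr)
}

#' First-order decline rate of log enrichment
#'
#' Least-squares slope of `ln(enrichment)` against time over a window,
#' returned as an absolute value (Log_Enrich per minute). For an exact
#' exponential decay `E0 * exp(-k t)` the estimate is `k`. Natural log is
#' used so the slope is the first-order rate constant; set
#' `base = "log10"` to report in decadic log units.
#'
#' @param series Tibble from [atom_fraction_enrichment()] (columns
#'   `time_min`, `enrichment`).
#' @param window Optional `c(start, end)` time window (minutes,
#'   inclusive); defaults to the full series.
#' @param base `"ln"` (default) or `"log10"`.
#' @return Rate (per minute, nonnegative scalar).
#' @export
log_enrichment_slope <- function(series, window = NULL, base = c("ln", "log10")) {
  base <- match.arg(base)
  stopifnot(all(c("time_min", "enrichment") %in% names(series)))
  df <- series
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time_min >= window[1],
                        .data$time_min <= window[2])
  }
  if (nrow(df) < 3) abort("Need at least 3 points in the fitting window.")
  if (any(df$enrichment <= 0)) {
    abort("All enrichments in the window must be positive for a log slope.")
  }
  slope <- unname(coef(lm(log(enrichment) ~ time_min, data = df))[2])
  rate <- abs(slope)
  if (base == "log10") rate <- rate / log(10)
  rate
}

#' Per-segment 18O-exchange rates of a MIMS assay
#'
#' Splits the trace at the protein- and effector-addition events, drops a
#' post-addition equilibration gap at the start of each later segment,
#' and reports the absolute log-enrichment decline rate per segment:
#' `pre_protein` (uncatalysed background), `post_protein`, and (when an
#' effector event is marked) `post_effector`.
#'
#' @param trace A [mims_trace()] with a `protein` event and optionally an
#'   `effector` event.
#' @param gap_min Equilibration gap (minutes) excluded after each
#'   addition before the slope is fitted.
#' @param base Log convention, see [log_enrichment_slope()].
#' @return A tibble with columns `segment`, `t_start`, `t_end`,
#'   `n_points`, `rate_per_min`.
#' @export
segment_rates <- function(trace, gap_min = 0.5, base = c("ln", "log10")) {
  base <- match.arg(base)
  stopifnot(inherits(trace, "mims_trace"))
  ev <- trace$events
  if (!"protein" %in% names(ev)) {
    abort("Trace must mark a `protein` addition event.")
  }
  series <- atom_fraction_enrichment(trace)
  t0 <- min(series$time_min); t_end <- max(series$time_min)
  bounds <- list(pre_protein = c(t0, ev[["protein"]]))
  if ("effector" %in% names(ev)) {
    if (ev[["effector"]] <= ev[["protein"]]) {
      abort("`effector` event must come after `protein`.")
    }
    bounds$post_protein <- c(ev[["protein"]] + gap_min, ev[["effector"]])
    bounds$post_effector <- c(ev[["effector"]] + gap_min, t_end)
  } else {
    bounds$post_protein <- c(ev[["protein"]] + gap_min, t_end)
  }
  purrr::imap_dfr(bounds, function(w, nm) {
    sub <- dplyr::filter(series, .data$time_min >= w[1],
                         .data$time_min <= w[2])
    if (nrow(sub) < 3) {
      abort(sprintf("Segment '%s' has fewer than 3 points after the %g min gap.",
                    nm, gap_min))
    }
    tibble::tibble(
      segment = nm, t_start = w[1], t_end = w[2], n_points = nrow(sub),
      rate_per_min = log_enrichment_slope(sub, base = base)
    )
  })
}

#' Segment rates relative to a reference maximum
#'
#' Expresses per-segment rates as a proportion of a reference maximum
#' rate (by default the largest rate in the table), the display convention
#' for comparing enzyme variants.
#'
#' @param rates Tibble from [segment_rates()].
#' @param reference_max Positive reference rate; defaults to
#'   `max(rates$rate_per_min)`.
#' @return The input tibble with an added `relative_rate` column.
#' @export
relative_rate_profile <- function(rates, reference_max = NULL) {
  stopifnot("rate_per_min" %in% names(rates))
  if (is.null(reference_max)) reference_max <- max(rates$rate_per_min)
  if (!is.finite(reference_max) || reference_max <= 0) {
    abort("`reference_max` must be positive.")
  }
  dplyr::mutate(rates, relative_rate = .data$rate_per_min / reference_max)
}
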