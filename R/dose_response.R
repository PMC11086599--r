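# Effector dose-response fitting: Hill, Michaelis-Menten and biphasic
# (basal + Hill) models, fitted by bounded nonlinear least squares with a
# deterministic multi-start grid, and compared by small-sample-corrected
# AIC alongside R^2.

.validate_curve <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("effector_uM", "rate") %in% names(data))) {
    abort("Curve must have columns `effector_uM` and `rate`.")
  }
  if (any(!is.finite(data$effector_uM)) || any(data$effector_uM < 0)) {
    abort("`effector_uM` must be finite and nonnegative.")
  }
  if (any(!is.finite(data$rate))) abort("`rate` must be finite.")
  if (length(unique(data$effector_uM)) < 5) {
    abort("Need at least 5 distinct effector concentrations to fit.")
  }
  data
}

.hill_fun <- function(x, v_max, k_half, h) {
  r <- ifelse(x == 0, 0, (x / k_half)^h)
  v_max * r / (1 + r)
}

.biphasic_fun <- function(x, v_max, k_half, h, basal) {
  basal + (v_max - basal) * .hill_fun(x, 1, k_half, h)
}

.model_spec <- function(model) {
  switch(model,
    hill = list(
      pars = c("v_max", "k_half_uM", "h"),
      fn = function(x, p) .hill_fun(x, p[["v_max"]], p[["k_half_uM"]], p[["h"]]),
      formula = rate ~ v_max * ifelse(effector_uM == 0, 0,
        (effector_uM / k_half_uM)^h / (1 + (effector_uM / k_half_uM)^h)),
      lower = c(v_max = 1e-12, k_half_uM = 1e-9, h = 0.01),
      upper = c(v_max = Inf, k_half_uM = Inf, h = 20)
    ),
    michaelis_menten = list(
      pars = c("v_max", "k_half_uM"),
      fn = function(x, p) .hill_fun(x, p[["v_max"]], p[["k_half_uM"]], 1),
      formula = rate ~ v_max * effector_uM / (k_half_uM + effector_uM),
      lower = c(v_max = 1e-12, k_half_uM = 1e-9),
      upper = c(v_max = Inf, k_half_uM = Inf)
    ),
    biphasic = list(
      pars = c("v_max", "k_half_uM", "h", "basal"),
      fn = function(x, p) .biphasic_fun(x, p[["v_max"]], p[["k_half_uM"]],
                                        p[["h"]], p[["basal"]]),
      formula = rate ~ basal + (v_max - basal) * ifelse(effector_uM == 0, 0,
        (effector_uM / k_half_uM)^h / (1 + (effector_uM / k_half_uM)^h)),
      lower = c(v_max = 1e-12, k_half_uM = 1e-9, h = 0.01, basal = 0),
      upper = c(v_max = Inf, k_half_uM = Inf, h = 20, basal = Inf)
    ),
    abort(sprintf("Unknown model '%s'.", model))
  )
}

# deterministic multi-start grid over (k_half, h, basal)
.start_grid <- function(model, data) {
  x <- data$effector_uM[data$effector_uM > 0]
  y <- data$rate
  k_starts <- unname(quantile(unique(x), c(0.1, 0.3, 0.5, 0.7, 0.9)))
  v0 <- max(y)
  b0 <- max(min(y), 0)
  h_starts <- if (model == "michaelis_menten") NA else c(0.5, 1, 2, 4)
  grid <- expand.grid(k_half_uM = k_starts, h = h_starts,
                      KEEP.OUT.ATTRS = FALSE)
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    s <- list(v_max = v0, k_half_uM = grid$k_half_uM[i])
    if (model != "michaelis_menten") s$h <- grid$h[i]
    if (model == "biphasic") s$basal <- b0
    s
  })
  starts
}

.fit_degenerate <- function(model, data) {
  m <- mean(data$rate)
  spec <- .model_spec(model)
  est <- setNames(rep(NA_real_, length(spec$pars)), spec$pars)
  est["v_max"] <- m
  if (model == "biphasic") est["basal"] <- m
  fitted <- rep(m, nrow(data))
  new_dose_fit(model, fit = NULL, estimates = est,
               std_errors = setNames(rep(NA_real_, length(est)), names(est)),
               data = data, fitted = fitted, degenerate = TRUE)
}

new_dose_fit <- function(model, fit, estimates, std_errors, data, fitted,
                         degenerate = FALSE) {
  res <- data$rate - fitted
  ss_tot <- sum((data$rate - mean(data$rate))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  n <- nrow(data)
  p <- sum(!is.na(estimates)) + 1 # + residual variance
  rss <- sum(res^2)
  aicc <- if (n - p - 1 > 0) {
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  } else NA_real_
  structure(list(
    model = model, fit = fit,
    params = tibble::tibble(term = names(estimates),
                            estimate = unname(estimates),
                            std_error = unname(std_errors[names(estimates)])),
    r_squared = r2, aicc = aicc, n = n, rss = rss,
    data = data, fitted = fitted, residuals = res,
    degenerate = degenerate
  ), class = "dose_fit")
}

.fit_model <- function(data, model) {
  data <- .validate_curve(data)
  if (sd(data$rate) < 1e-12 * max(abs(data$rate), 1)) {
    return(.fit_degenerate(model, data))
  }
  spec <- .model_spec(model)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 500)
  best <- NULL
  for (start in .start_grid(model, data)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        spec$formula, data = data, start = start,
        lower = spec$lower[names(start)], upper = spec$upper[names(start)],
        control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- sum(resid(fit)^2)
    if (is.null(best) || dev < best$dev - 1e-300 ||
        (dev < best$dev)) {
      best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "Nonlinear least squares failed to converge for the %s model from any start.",
      model))
  }
  fit <- best$fit
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(est)),
                                              names(est)))
  new_dose_fit(model, fit = fit, estimates = est, std_errors = se,
               data = data, fitted = as.numeric(predict(fit)))
}

#' Fit a Hill activation model to a dose-response curve
#'
#' Nonlinear least squares of `v = v_max * x^h / (k_half^h + x^h)` with
#' positivity bounds and a deterministic multi-start grid over
#' `(k_half, h)` to avoid local minima. Replicates are fitted as
#' individual points.
#'
#' @param data Data frame with columns `effector_uM`, `rate` (and
#'   optionally `replicate`); at least 5 distinct concentrations.
#' @return A `dose_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @examples
#' curve <- generate_response_curve(noise_sd = 0, seed = 1)
#' glance(fit_hill(curve))
#' @export
fit_hill <- function(data) .fit_model(data, "hill")

#' Fit a Michaelis-Menten (hyperbolic) model
#'
#' The Hill model with slope fixed at `h = 1`:
#' `v = v_max * x / (k_half + x)`.
#'
#' @inheritParams fit_hill
#' @return A `dose_fit` object.
#' @export
fit_michaelis_menten <- function(data) .fit_model(data, "michaelis_menten")

#' Fit a biphasic (basal + Hill) model
#'
#' `v = basal + (v_max - basal) * x^h / (k_half^h + x^h)` with
#' `basal >= 0`; describes variants with effector-independent activity
#' plus a further effector-dependent increase. Reduces to the Hill model
#' when `basal = 0`. Constant-activity data yield a flagged degenerate
#' result with `basal = v_max = mean(rate)`.
#'
#' @inheritParams fit_hill
#' @return A `dose_fit` object.
#' @export
fit_biphasic <- function(data) .fit_model(data, "biphasic")

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of observed against fitted values.
#'
#' @param observed,fitted Equal-length numeric vectors (>= 2 points);
#'   `observed` must have nonzero variance.
#' @return R-squared (scalar, <= 1).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) abort("Lengths must match.")
  if (length(observed) < 2) abort("Need at least 2 points.")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("R-squared undefined: observed values have zero variance.")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Fit and rank candidate dose-response models
#'
#' Fits the Hill, Michaelis-Menten and biphasic models to the same curve
#' and ranks them by small-sample-corrected AIC (AICc); R-squared and the
#' R-squared gain over the best model are reported alongside. Individual
#' fit failures are propagated as rows with an `error` message.
#'
#' @inheritParams fit_hill
#' @return A tibble, one row per model, sorted by AICc, with the fitted
#'   `dose_fit` objects in a list-column `fit`.
#' @export
compare_models <- function(data) {
  data <- .validate_curve(data)
  models <- c("hill", "michaelis_menten", "biphasic")
  rows <- purrr::map(models, function(m) {
    f <- tryCatch(.fit_model(data, m), error = function(e) e)
    if (inherits(f, "error")) {
      tibble::tibble(model = m, r_squared = NA_real_, aicc = NA_real_,
                     degenerate = NA, error = conditionMessage(f),
                     fit = list(NULL))
    } else {
      tibble::tibble(model = m, r_squared = f$r_squared, aicc = f$aicc,
                     degenerate = f$degenerate, error = NA_character_,
                     fit = list(f))
    }
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$aicc)
  dplyr::mutate(out,
    delta_aicc = .data$aicc - min(.data$aicc, na.rm = TRUE),
    delta_r_squared = max(.data$r_squared, na.rm = TRUE) - .data$r_squared)
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("<dose_fit: %s>%s n = %d, R^2 = %s, AICc = %s\n",
              x$model, if (x$degenerate) " [degenerate]" else "",
              x$n,
              formatC(x$r_squared, digits = 4, format = "g"),
              formatC(x$aicc, digits = 4, format = "g")))
  est <- setNames(x$params$estimate, x$params$term)
  cat("  ", paste(sprintf("%s = %s", names(est),
                          formatC(est, digits = 4, format = "g")),
                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.dose_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  spec <- .model_spec(object$model)
  p <- setNames(object$params$estimate, object$params$term)
  spec$fn(newdata$effector_uM, p)
}

#' @rdname tidy.dose_fit
#' @export
glance.dose_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared, aicc = x$aicc,
                 rss = x$rss, n = x$n, degenerate = x$degenerate)
}

#' Tidy a dose-response fit
#'
#' `tidy()` returns one row per fitted parameter (estimate and asymptotic
#' standard error); `glance()` returns a one-row model summary.
#'
#' @param x A `dose_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dose_fit <- function(x, ...) {
  dplyr::rename(x$params, std.error = "std_error")
}
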