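# Configuration, file I/O and the end-to-end pipeline commands. Every
# command is a thin wrapper over the library functions with strict input
# validation, and each run writes a provenance record (config hash, seed,
# package version) so outputs are traceable.

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over the packaged default
#' (a Cyanobium-like carboxysome: 20 mM external HCO3-, pH 8.0,
#' CA factor 100,000, half-maximal activation at 18 uM RuBP, Hill slope
#' 2.214), and rejects unknown keys. Every numeric key carries its unit
#' in its name.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged default.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  default <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                         package = "carboxsim",
                                         mustWork = TRUE))
  cfg <- default
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    .check_keys(user, default, "config")
    cfg <- modifyList(default, user)
  }
  structure(cfg, class = c("run_config", "list"))
}

.check_keys <- function(user, default, where) {
  if (!is.list(user)) return(invisible())
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown key(s) under %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(default[[k]])) .check_keys(user[[k]], default[[k]],
                                           paste(where, k, sep = "$"))
  }
  invisible()
}

#' Build a carboxysome model from a configuration
#'
#' @param config A [load_config()] result (or `NULL` for the default).
#' @param regulated Logical; RuBP-regulated carboxysomal CA?
#' @return A [carboxysome_model()].
#' @export
model_from_config <- function(config = NULL, regulated = TRUE) {
  if (is.null(config)) config <- load_config()
  m <- config$model
  carboxysome_model(
    ca_carboxysome = ca_kinetics(
      k1 = m$k1_per_s, k2 = m$k2_per_mM_s,
      ca_factor = m$ca_factor_carboxysome, regulated = regulated,
      hill = hill_activation(k_half_uM = m$k_half_uM, h = m$hill_slope)),
    ca_unstirred = ca_kinetics(k1 = m$k1_per_s, k2 = m$k2_per_mM_s,
                               ca_factor = 1),
    rubisco = rubisco_params(
      kcat_c = m$kcat_c_per_s, km_co2_uM = m$km_co2_uM,
      km_o2_mM = m$km_o2_mM, kcat_o = m$kcat_o_per_s,
      km_rubp_uM = m$km_rubp_uM, e_sites_mM = m$e_sites_mM),
    external = c(co2 = m$external_co2_mM, hco3 = m$external_hco3_mM,
                 h = 10^(-m$external_ph) * 1000, o2 = m$external_o2_mM,
                 rubp = 0.001),
    diameter_nm = m$diameter_nm,
    unstirred_volume_ratio = m$unstirred_volume_ratio,
    transport_ext = unlist(m$transport_ext_per_s),
    transport_shell = unlist(m$transport_shell_per_s),
    n_h_carboxylation = m$n_h_carboxylation,
    pka_rubp = m$pka_rubp,
    speciation = m$speciation,
    clamp_rubp = m$clamp_rubp
  )
}

.provenance <- function(config) {
  list(config_hash = rlang::hash(unclass(config)),
       seed = config$seed,
       package = "carboxsim",
       version = as.character(utils::packageVersion("carboxsim")))
}

#' Run paired regulated/unregulated RuBP sweeps and write results
#'
#' Runs the carboxysome model sweep twice -- with and without the
#' RuBP-dependent CA -- over the configured RuBP grid, writes one tidy
#' CSV per model plus a JSON summary (luminal pH shift at the lowest RuBP
#' level, regulated/unregulated carboxylation ratio at the highest level,
#' and the provenance record).
#'
#' @param config A [load_config()] result, a YAML path, or `NULL` for
#'   the default configuration.
#' @param output_dir Output directory (created if absent); defaults to
#'   the configured `output_dir`.
#' @return Invisibly, a list with the two sweep tibbles, the summary
#'   list, and the output file paths.
#' @export
run_sweep <- function(config = NULL, output_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (is.null(config)) config <- load_config()
  output_dir <- output_dir %||% config$output_dir
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  grid <- 10^seq(log10(config$sweep$rubp_min_mM),
                 log10(config$sweep$rubp_max_mM),
                 length.out = config$sweep$n_levels)
  tol <- config$solver$tol_mM_s
  reg <- run_rubp_sweep(model_from_config(config, regulated = TRUE),
                        rubp_levels_mM = grid, tol = tol)
  unreg <- run_rubp_sweep(model_from_config(config, regulated = FALSE),
                          rubp_levels_mM = grid, tol = tol)

  summary <- list(
    ph_shift_low_rubp = unreg$ph_cbx[1] - reg$ph_cbx[1],
    ph_regulated_low_rubp = reg$ph_cbx[1],
    ph_unregulated_low_rubp = unreg$ph_cbx[1],
    carboxylation_ratio_high_rubp =
      reg$kcat_c_eff_s[nrow(reg)] / unreg$kcat_c_eff_s[nrow(unreg)],
    provenance = .provenance(config)
  )

  paths <- file.path(output_dir, c("sweep_regulated.csv",
                                   "sweep_unregulated.csv",
                                   "sweep_summary.json"))
  write.csv(reg, paths[1], row.names = FALSE)
  write.csv(unreg, paths[2], row.names = FALSE)
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(regulated = reg, unregulated = unreg, summary = summary,
                 paths = paths))
}

#' Read a dose-response CSV
#'
#' Strictly validated reader for the package's response-curve dialect:
#' comma-separated with a header row and columns `effector_uM`, `rate`
#' and optionally `replicate`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_response_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  if (!all(c("effector_uM", "rate") %in% names(df))) {
    abort(sprintf("%s must have columns `effector_uM` and `rate`.", path))
  }
  extra <- setdiff(names(df), c("effector_uM", "replicate", "rate"))
  if (length(extra) > 0) {
    abort(sprintf("Unexpected column(s) in %s: %s", path,
                  paste(extra, collapse = ", ")))
  }
  df
}

#' Read a MIMS trace CSV (plus events)
#'
#' Reads a trace CSV with columns `time_min`, `mz44`..`mz49` and an
#' events specification: either a named numeric vector or a two-column
#' CSV (`label`, `time_min`).
#'
#' @param path Trace CSV path.
#' @param events Named numeric vector of event times, or the path to an
#'   events CSV.
#' @return A [mims_trace()].
#' @export
read_trace_csv <- function(path, events = numeric()) {
  df <- tibble::as_tibble(read.csv(path))
  if (is.character(events)) {
    ev <- read.csv(events)
    if (!all(c("label", "time_min") %in% names(ev))) {
      abort("Events CSV must have columns `label` and `time_min`.")
    }
    events <- setNames(ev$time_min, ev$label)
  }
  mims_trace(df, events = events)
}

#' Fit dose-response models to a CSV and write the results
#'
#' @param path Response CSV (see [read_response_csv()]).
#' @param model One of `"all"` (rank all candidates), `"hill"`,
#'   `"michaelis_menten"`, `"biphasic"`.
#' @param out_json Optional path for a JSON report of the fit(s).
#' @param fitted_csv Optional path for a fitted-curve CSV (200-point
#'   dense grid) for plotting.
#' @return The `dose_fit` (or [compare_models()] tibble) invisibly.
#' @export
run_fit <- function(path, model = c("all", "hill", "michaelis_menten",
                                    "biphasic"),
                    out_json = NULL, fitted_csv = NULL) {
  model <- match.arg(model)
  data <- read_response_csv(path)
  if (model == "all") {
    cmp <- compare_models(data)
    report <- lapply(seq_len(nrow(cmp)), function(i) {
      f <- cmp$fit[[i]]
      c(list(model = cmp$model[i], aicc = cmp$aicc[i],
             delta_aicc = cmp$delta_aicc[i], r_squared = cmp$r_squared[i]),
        if (!is.null(f)) list(parameters = as.list(setNames(
          f$params$estimate, f$params$term))))
    })
    best <- cmp$fit[[1]]
    result <- cmp
  } else {
    f <- switch(model, hill = fit_hill(data),
                michaelis_menten = fit_michaelis_menten(data),
                biphasic = fit_biphasic(data))
    report <- list(model = f$model, r_squared = f$r_squared, aicc = f$aicc,
                   degenerate = f$degenerate,
                   parameters = as.list(setNames(f$params$estimate,
                                                 f$params$term)),
                   std_errors = as.list(setNames(f$params$std_error,
                                                 f$params$term)))
    best <- f
    result <- f
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(fitted_csv) && !is.null(best)) {
    x <- 10^seq(log10(max(min(data$effector_uM[data$effector_uM > 0]), 1e-3)),
                log10(max(data$effector_uM)), length.out = 200)
    write.csv(tibble::tibble(effector_uM = x,
                             rate = predict(best,
                                            tibble::tibble(effector_uM = x))),
              fitted_csv, row.names = FALSE)
  }
  invisible(result)
}

#' Compute MIMS segment rates from CSV inputs and write the results
#'
#' @param path Trace CSV (see [read_trace_csv()]).
#' @param events Named event-time vector or events CSV path.
#' @param out_json Optional JSON output path.
#' @param gap_min Post-addition equilibration gap (minutes).
#' @param relative Also report rates relative to the maximum segment rate.
#' @return The segment-rate tibble invisibly.
#' @export
run_mims <- function(path, events, out_json = NULL, gap_min = 0.5,
                     relative = TRUE) {
  trace <- read_trace_csv(path, events)
  rates <- segment_rates(trace, gap_min = gap_min)
  if (relative) rates <- relative_rate_profile(rates)
  if (!is.null(out_json)) {
    jsonlite::write_json(rates, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(rates)
}

#' Materialise a complete synthetic demo dataset tree
#'
#' Writes, under `dir`: a wild-type MIMS trace CSV with its events CSV,
#' and one dose-response CSV per variant class from
#' [generate_mutant_panel()] -- the same CSV dialects the analysis
#' commands read. Fully seeded.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulate_mims_trace(seed = seed)
  trace_path <- file.path(dir, "mims_trace.csv")
  events_path <- file.path(dir, "mims_events.csv")
  write.csv(tr$data, trace_path, row.names = FALSE)
  write.csv(data.frame(label = names(tr$events),
                       time_min = unname(tr$events)),
            events_path, row.names = FALSE)
  panel <- generate_mutant_panel(seed = seed)
  panel_paths <- purrr::imap_chr(panel, function(df, nm) {
    p <- file.path(dir, sprintf("response_%s.csv", nm))
    write.csv(df, p, row.names = FALSE)
    p
  })
  invisible(c(trace = trace_path, events = events_path, panel_paths))
}
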