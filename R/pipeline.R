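#' Derive a reproducible per-stage seed from the global seed
#'
#' Fans one global seed out into independent, deterministic sub-seeds so any
#' stage can be rerun in isolation with the same stream.
#'
#' @param seed global integer seed.
#' @param label stage label, e.g. `"ensemble:V1"`.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 1000003
  as.integer(((seed %% 1000003) * 2017 + h) %% 2147483647)
}

#' Analysis configuration
#'
#' @param variants named list of [variant_spec]s (default [make_variants()]).
#' @param params classical [transport_params] (ground truth for the emulated
#'   ensembles and starting point of the fits).
#' @param ensemble an [ensemble_spec] for the MD-like traces.
#' @param experimental_peaks optional named numeric vector of experimental
#'   sensor peak times (ps) per variant; when given, the quantum correction
#'   is fitted to them, otherwise `quantum_Q` is applied as-is.
#' @param quantum_Q quantum-correction factor used when no experimental peak
#'   times are supplied (default 3.1).
#' @param do_fit fit `D_B`, `D_C`, `k_h` to the emulated ensemble of each
#'   variant (slower); otherwise the configured parameters are used directly.
#' @param n_walkers Monte Carlo walkers per variant for the sampled pathway
#'   fractions (0 disables the MC stage; exact fractions are always computed).
#' @param t_max,dt output trajectory grid (ps).
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param seed global seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(variants = make_variants(),
                            params = transport_params(),
                            ensemble = ensemble_spec(),
                            experimental_peaks = NULL,
                            quantum_Q = 3.1,
                            do_fit = TRUE,
                            n_walkers = 1e5,
                            t_max = 50, dt = 0.05,
                            out_dir = NULL, seed = 1) {
  if (quantum_Q < 1) stop("quantum_Q must be >= 1")
  structure(list(variants = variants, params = params, ensemble = ensemble,
                 experimental_peaks = experimental_peaks,
                 quantum_Q = quantum_Q, do_fit = do_fit,
                 n_walkers = n_walkers, t_max = t_max, dt = dt,
                 out_dir = out_dir, seed = seed),
            class = "analysis_config")
}

#' Run the full per-variant analysis
#'
#' For every variant: build the idealized structure and classical rate
#' network; optionally emulate a noisy MD-like ensemble and re-fit the
#' transport coefficients from it; calibrate (or apply) the global quantum
#' correction; integrate classical and quantum-corrected master equations;
#' compute peak metrics and the exact (and optionally Monte Carlo) pathway
#' decomposition of sensor-arriving energy. Writes one bundle of files per
#' variant when `out_dir` is set; numeric outputs are reproducible
#' bit-for-bit under a fixed config and seed.
#'
#' @param config an [analysis_config].
#' @return named list per variant with elements `network`, `fit`,
#'   `network_quantum`, `Q`, `traj_classical`, `traj_quantum`, `peaks`
#'   (classical/quantum data.frames), `fractions` (exact), `fractions_mc`
#'   (or `NULL`), `sensor`; plus attribute `"q_fit"` when the quantum
#'   correction was fitted.
#' @export
run_variant_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  times <- seq(0, config$t_max, by = config$dt)
  out <- list()
  nets <- list()
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", label, conditionMessage(e)), call. = FALSE))
  }
  for (vn in names(config$variants)) {
    v <- config$variants[[vn]]
    built <- stage(paste0("network:", vn),
                   build_variant_network(v, config$params, n_res = v$n_res))
    fit <- NULL
    net_classical <- built$network
    if (isTRUE(config$do_fit)) {
      ens_spec <- config$ensemble
      ens_spec$seed <- stage_seed(config$seed, paste0("ensemble:", vn))
      ens <- stage(paste0("ensemble:", vn),
                   simulate_noisy_ensemble(built$network, ens_spec))
      fit <- stage(paste0("fit:", vn),
                   fit_transport_coefficients(ens$observed, built$template))
      p_fit <- config$params
      p_fit[c("D_B", "D_C", "k_h")] <- fit$par[c("D_B", "D_C", "k_h")]
      net_classical <- template_network(built$template, p_fit)
    }
    out[[vn]] <- list(variant = v, structure = built$structure,
                      network = net_classical, fit = fit,
                      sensor = res_node(v$sensor))
    nets[[vn]] <- net_classical
  }
  q_fit <- NULL
  if (!is.null(config$experimental_peaks)) {
    sensors <- vapply(out, function(x) x$sensor, character(1))
    q_fit <- fit_quantum_correction(nets, config$experimental_peaks, sensors)
    Q <- unname(q_fit$par["Q"])
  } else Q <- config$quantum_Q
  for (vn in names(out)) {
    b <- out[[vn]]
    net_q <- apply_quantum_correction(b$network, Q)
    b$Q <- Q
    b$network_quantum <- net_q
    b$traj_classical <- integrate_master_equation(b$network, times = times)
    b$traj_quantum <- integrate_master_equation(net_q, times = times)
    b$peaks <- list(classical = peak_metrics(b$traj_classical),
                    quantum = peak_metrics(b$traj_quantum))
    b$fractions <- stage(paste0("pathways:", vn),
                         exact_pathway_fractions(net_q, HEATER_NODE, b$sensor,
                                                 times = times))
    b$fractions_mc <- if (config$n_walkers > 0) {
      rec <- sample_jump_chain(net_q, HEATER_NODE, b$sensor,
                               n_walkers = config$n_walkers,
                               t_max = config$t_max,
                               seed = stage_seed(config$seed, paste0("mc:", vn)))
      mc_pathway_fractions(rec, times = times)
    }
    out[[vn]] <- b
  }
  if (!is.null(q_fit)) attr(out, "q_fit") <- q_fit
  if (!is.null(config$out_dir)) write_report_bundle(out, config)
  out
}

write_report_bundle <- function(results, config) {
  root <- config$out_dir
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (vn in names(results)) {
    b <- results[[vn]]
    d <- file.path(root, vn)
    dir.create(d, showWarnings = FALSE)
    write_network_json(b$network, file.path(d, "network_classical.json"))
    write_network_json(b$network_quantum, file.path(d, "network_quantum.json"))
    write_trajectory_csv(b$traj_classical, file.path(d, "traj_classical.csv"))
    write_trajectory_csv(b$traj_quantum, file.path(d, "traj_quantum.csv"))
    jsonlite::write_json(list(classical = b$peaks$classical,
                              quantum = b$peaks$quantum,
                              Q = b$Q, sensor = b$sensor),
                         file.path(d, "peaks.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_fractions_csv(b$fractions, file.path(d, "fractions_exact.csv"))
    summ <- list(exact = as.list(fractions_at(b$fractions, config$t_max)))
    if (!is.null(b$fractions_mc)) {
      write_fractions_csv(b$fractions_mc, file.path(d, "fractions_mc.csv"))
      summ$monte_carlo <- as.list(fractions_at(b$fractions_mc, config$t_max))
      summ$n_walkers <- config$n_walkers
    }
    jsonlite::write_json(summ, file.path(d, "fractions_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(b$fit))
      jsonlite::write_json(list(par = as.list(b$fit$par),
                                objective = b$fit$objective,
                                iterations = b$fit$iterations,
                                converged = b$fit$converged),
                           file.path(d, "transport_fit.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  log <- c(sprintf("vetflow %s", as.character(utils::packageVersion("vetflow"))),
           sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("global seed %d", config$seed),
           sprintf("quantum Q %.6g%s", results[[1]]$Q,
                   if (is.null(attr(results, "q_fit"))) " (configured)" else " (fitted)"),
           sprintf("params: %s",
                   paste(sprintf("%s=%.6g", names(unlist(config$params)),
                                 unlist(config$params)), collapse = " ")),
           sprintf("ensemble: n_traj=%d t_max=%g dt=%g sigma=%.3g seed policy: stage_seed",
                   config$ensemble$n_traj, config$ensemble$t_max,
                   config$ensemble$dt, config$ensemble$sigma),
           sprintf("variants: %s", paste(names(results), collapse = " ")))
  writeLines(log, file.path(root, "run_log.txt"))
  invisible(root)
}
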