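#' Network template for parameter fitting
#'
#' Freezes the structural ingredients of a network (structure, detected
#' hydrogen bonds and heater contacts, heater residue) so that candidate
#' transport parameters can be swapped in cheaply during optimization.
#'
#' @param structure a [vet_structure].
#' @param heater heater residue number.
#' @param params a [transport_params] supplying the detection cutoffs and any
#'   parameters held fixed.
#' @return An object of class `network_template`.
#' @export
network_template <- function(structure, heater, params = transport_params()) {
  hb <- detect_hydrogen_bonds(structure, params$hb_cutoff, params$hb_angle_min)
  hc <- detect_heater_contacts(structure, heater, params$hc_cutoff)
  structure(list(structure = structure, heater = heater, hb_pairs = hb,
                 hc_pairs = hc, params = params),
            class = "network_template")
}

#' Build the network of a template under given parameters
#' @param template a [network_template].
#' @param params a [transport_params]; defaults to the template's.
#' @return An `energy_network`.
#' @export
template_network <- function(template, params = template$params) {
  assemble_network(template$structure, template$hb_pairs, template$hc_pairs,
                   params, heater = template$heater)
}

fit_result <- function(par, objective, iterations, converged, extra = list()) {
  structure(c(list(par = par, objective = objective, iterations = iterations,
                   converged = converged), extra),
            class = "vet_fit")
}

#' @export
print.vet_fit <- function(x, ...) {
  cat(sprintf("<vet_fit> %s; objective %.6g; %d evaluations; converged: %s\n",
              paste(sprintf("%s=%.4g", names(x$par), x$par), collapse = " "),
              x$objective, x$iterations, x$converged))
  invisible(x)
}

#' Fit transport coefficients to observed residue-energy traces
#'
#' Minimizes the summed squared residuals of the per-residue energies
#' `E_j(t)` over all residues and grid times, between the master-equation
#' model rebuilt from `template` and the observed traces (e.g. an MD-like
#' ensemble average). The cooling rate `k_s` is always held fixed (it is
#' taken from experiment, not fitted). A coarse logarithmic grid scan seeds a
#' bounded derivative-free simplex search in log-parameter space.
#'
#' @param observed an `energy_trajectory` of observed traces; node columns
#'   are matched by name, extra model nodes (heater pool, solvent) ignored.
#' @param template a [network_template].
#' @param free character subset of `c("D_B", "D_C", "k_h")` to fit; the rest
#'   are held at `template$params`.
#' @param lower,upper named bounds on the free parameters (defaults
#'   `1e-3`..`1e3` for coefficients, `1e-3`..`1e2` for `k_h`).
#' @param n_grid grid points per free parameter in the pre-scan.
#' @return A `vet_fit` with fields `par` (all transport parameters, fitted
#'   and fixed), `objective`, `iterations`, `converged`, and `model` (the
#'   fitted trajectory).
#' @export
fit_transport_coefficients <- function(observed, template,
                                       free = c("D_B", "D_C", "k_h"),
                                       lower = NULL, upper = NULL,
                                       n_grid = 5) {
  stopifnot(inherits(observed, "energy_trajectory"))
  if (length(free) > 0L)
    free <- match.arg(free, c("D_B", "D_C", "k_h"), several.ok = TRUE)
  p0 <- template$params
  times <- observed$times
  obs_nodes <- intersect(observed$nodes,
                         res_node(residue_numbers(template$structure)))
  if (length(obs_nodes) == 0L) stop("observed traces share no residue with the template")
  Yobs <- observed$energies[, obs_nodes, drop = FALSE]

  make_params <- function(vals) {
    p <- p0
    p[names(vals)] <- vals
    p
  }
  objective <- function(vals) {
    p <- make_params(vals)
    net <- template_network(template, p)
    traj <- integrate_master_equation(net, times = times)
    sum((traj$energies[, obs_nodes, drop = FALSE] - Yobs)^2)
  }

  if (length(free) == 0L) {
    obj <- objective(setNames(numeric(0), character(0)))
    net <- template_network(template, p0)
    return(fit_result(unlist(p0[c("D_B", "D_C", "k_h", "k_s")]), obj, 1L, TRUE,
                      list(model = integrate_master_equation(net, times = times))))
  }

  def_lo <- c(D_B = 1e-3, D_C = 1e-3, k_h = 1e-3)
  def_hi <- c(D_B = 1e3, D_C = 1e3, k_h = 1e2)
  lo <- def_lo[free]; hi <- def_hi[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  # coarse log-grid pre-scan
  grids <- lapply(free, function(f) exp(seq(log(lo[f]), log(hi[f]),
                                            length.out = n_grid)))
  cand <- as.matrix(expand.grid(grids))
  colnames(cand) <- free
  scan_obj <- apply(cand, 1, function(v) objective(setNames(v, free)))
  start <- cand[which.min(scan_obj), ]

  evals <- length(scan_obj)
  fn_log <- function(lp) {
    v <- pmin(pmax(exp(lp), lo), hi)  # box projection
    evals <<- evals + 1L
    objective(setNames(v, free))
  }
  opt <- optim(log(start), fn_log, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  fitted <- setNames(pmin(pmax(exp(opt$par), lo), hi), free)
  p_fit <- make_params(fitted)
  net <- template_network(template, p_fit)
  fit_result(unlist(p_fit[c("D_B", "D_C", "k_h", "k_s")]), opt$value,
             evals, opt$convergence == 0,
             list(model = integrate_master_equation(net, times = times),
                  free = free))
}

#' Fit the global quantum-correction factor
#'
#' A single scalar `Q >= 1` multiplies the heater rate and all backbone and
#' contact rates (cooling untouched) of every variant's classical network.
#' `Q` is chosen to minimize the summed squared difference between model
#' sensor peak times and experimental peak times, all variants weighted
#' equally; a grid scan over the bounds seeds a golden-section refinement.
#'
#' @param networks named list of classical `energy_network`s, one per variant.
#' @param peak_times named numeric vector of experimental peak times (ps);
#'   names must match `networks`.
#' @param sensors named character/numeric vector of sensor nodes per variant.
#' @param bounds numeric length-2 search interval for `Q`.
#' @param times integration grid used for the model peak times.
#' @return A `vet_fit` with `par = c(Q = ...)` and per-variant model peak
#'   times in `$model_peaks`.
#' @export
fit_quantum_correction <- function(networks, peak_times, sensors,
                                   bounds = c(1, 10),
                                   times = seq(0, 50, by = 0.02)) {
  if (length(peak_times) == 0L) stop("no experimental peak times given")
  vn <- names(peak_times)
  stopifnot(!is.null(vn), all(vn %in% names(networks)), all(vn %in% names(sensors)))
  model_peaks <- function(Q) {
    vapply(vn, function(v) {
      net <- apply_quantum_correction(networks[[v]], Q)
      tr <- sensor_transient(integrate_master_equation(net, times = times),
                             sensors[[v]])
      unname(quad_peak(tr$time, tr$energy)["time"])
    }, numeric(1))
  }
  evals <- 0L
  objective <- function(Q) {
    evals <<- evals + 1L
    sum((model_peaks(Q) - peak_times)^2)
  }
  qs <- seq(bounds[1], bounds[2], length.out = 25)
  os <- vapply(qs, objective, numeric(1))
  b <- which.min(os)
  lo <- qs[max(1L, b - 1L)]; hi <- qs[min(length(qs), b + 1L)]
  opt <- optimize(objective, c(lo, hi), tol = 1e-5)
  Q <- max(1, opt$minimum)
  fit_result(c(Q = Q), opt$objective, evals, TRUE,
             list(model_peaks = model_peaks(Q), experimental = peak_times))
}

#' Fit the solvent cooling rate from a transient tail
#'
#' Log-linear least squares on the post-peak exponential tail of a transient:
#' `log y = a - k_s t` for `t >= tail_start`.
#'
#' @param transient data.frame with columns `time` and a signal column
#'   (second column; `energy` or `signal`).
#' @param tail_start start of the fit window (ps); must lie after the peak.
#' @return list with `k_s` (1/ps), `dissipation_time` (`1/k_s`, ps), and the
#'   underlying `lm` fit.
#' @export
fit_cooling_rate <- function(transient, tail_start) {
  t <- transient[[1]]
  y <- transient[[2]]
  pk <- t[which.max(y)]
  if (tail_start < pk)
    stop(sprintf("tail_start (%.3g ps) precedes the peak (%.3g ps)", tail_start, pk))
  sel <- t >= tail_start
  if (sum(sel) < 3L) stop("too few points beyond tail_start")
  if (any(y[sel] <= 0)) stop("non-positive transient values in the tail")
  fit <- lm(log(y[sel]) ~ t[sel])
  k_s <- -unname(coef(fit)[2])
  list(k_s = k_s, dissipation_time = 1 / k_s, fit = fit)
}
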