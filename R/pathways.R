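#' Classify a transport path by its edge classes
#'
#' A path is `HC` if it traversed any heater-contact edge, else `HB` if it
#' traversed any interstrand hydrogen bond, else `BB` (solely backbone).
#' HEAT and COOL labels are transparent to classification. The precedence
#' HC > HB reflects that heater contacts, emanating from the heater itself,
#' occur before any hydrogen-bond step on a mixed path.
#'
#' @param edge_classes character vector of edge-class labels along the path.
#' @return one of `"BB"`, `"HB"`, `"HC"`.
#' @export
classify_path <- function(edge_classes) {
  bad <- setdiff(edge_classes, EDGE_CLASSES)
  if (length(bad) > 0L)
    stop(sprintf("unknown edge class: %s", paste(bad, collapse = ",")))
  if ("HC" %in% edge_classes) "HC"
  else if ("HB" %in% edge_classes) "HB"
  else "BB"
}

# directed flow list of a network: data.frame(from, to, rate, class) with
# intramolecular edges expanded to both directions
directed_flows <- function(network) {
  e <- network$edges[network$edges$rate > 0, , drop = FALSE]
  sym <- e[e$class %in% INTRA_CLASSES, , drop = FALSE]
  data.frame(from = c(e$i, sym$j), to = c(e$j, sym$i),
             rate = c(e$rate, sym$rate), class = c(e$class, sym$class),
             stringsAsFactors = FALSE)
}

new_pathway_fractions <- function(times, BB, HB, HC, total, method) {
  structure(list(times = times,
                 fractions = data.frame(time = times, BB = BB, HB = HB, HC = HC,
                                        total_arrived = total),
                 method = method),
            class = "pathway_fractions")
}

#' @export
print.pathway_fractions <- function(x, ...) {
  f <- x$fractions[nrow(x$fractions), ]
  cat(sprintf(paste0("<pathway_fractions> (%s) at %.3g ps: BB=%.3f HB=%.3f ",
                     "HC=%.3f (arrived %.3f)\n"),
              x$method, f$time, f$BB, f$HB, f$HC, f$total_arrived))
  invisible(x)
}

#' Exact pathway-class decomposition of sensor-arriving energy
#'
#' Augments every node with two binary flags (hydrogen bond seen, heater
#' contact seen) and makes the sensor absorbing per flag combination. The
#' expanded system is still a linear constant-coefficient master equation and
#' is integrated exactly, giving the cumulative fraction of sensor-arriving
#' energy on solely-backbone (BB), hydrogen-bond (HB) and heater-contact (HC)
#' pathway classes at every grid time. Energy is counted at first passage;
#' recrossings after first arrival are not counted.
#'
#' @param network an `energy_network`.
#' @param source starting node name (residue `"Rk"` or `"HEATER_POOL"`).
#' @param sensor sensor node name.
#' @param times time grid (ps), as in [integrate_master_equation()].
#' @return A `pathway_fractions` object; fractions are `NA` where no energy
#'   has arrived yet.
#' @export
exact_pathway_fractions <- function(network, source, sensor,
                                    times = seq(0, 50, by = 0.05)) {
  if (is.numeric(source)) source <- res_node(source)
  if (is.numeric(sensor)) sensor <- res_node(sensor)
  stopifnot(source %in% network$nodes, sensor %in% network$nodes)
  fl <- directed_flows(network)
  reach <- reachable_from(fl, source)
  if (!(sensor %in% reach)) stop("sensor not reachable from source")

  transient <- setdiff(network$nodes, c(sensor, SOLVENT_NODE))
  states <- c(outer(transient, c("00", "10", "01", "11"), paste, sep = "|"))
  flag_of <- c("00" = 1L, "10" = 2L, "01" = 3L, "11" = 4L)  # hb,hc bits
  absorb <- c("SENS|00", "SENS|10", "SENS|01", "SENS|11", SOLVENT_NODE)
  all_states <- c(states, absorb)
  n <- length(all_states)
  idx <- setNames(seq_len(n), all_states)
  A <- matrix(0, n, n, dimnames = list(all_states, all_states))
  upd_flag <- function(f, class) {
    hb <- f %in% c("10", "11"); hc <- f %in% c("01", "11")
    if (class == "HB") hb <- TRUE
    if (class == "HC") hc <- TRUE
    paste0(as.integer(hb), as.integer(hc))
  }
  for (f in c("00", "10", "01", "11")) {
    for (k in seq_len(nrow(fl))) {
      from <- fl$from[k]; to <- fl$to[k]
      if (from == sensor || from == SOLVENT_NODE) next
      s_from <- idx[paste(from, f, sep = "|")]
      f2 <- upd_flag(f, fl$class[k])
      s_to <- if (to == SOLVENT_NODE) idx[SOLVENT_NODE]
              else if (to == sensor) idx[paste0("SENS|", f2)]
              else idx[paste(to, f2, sep = "|")]
      A[s_to, s_from] <- A[s_to, s_from] + fl$rate[k]
      A[s_from, s_from] <- A[s_from, s_from] - fl$rate[k]
    }
  }
  e0 <- setNames(numeric(n), all_states)
  if (source == sensor) stop("source must differ from sensor")
  e0[paste(source, "00", sep = "|")] <- 1
  traj <- integrate_master_equation(A, initial = e0, times = times)
  Es <- traj$energies
  arr <- Es[, paste0("SENS|", c("00", "10", "01", "11")), drop = FALSE]
  total <- rowSums(arr)
  hc <- rowSums(arr[, c("SENS|01", "SENS|11"), drop = FALSE])
  hb <- arr[, "SENS|10"]
  bb <- arr[, "SENS|00"]
  frac <- function(x) ifelse(total > 0, x / total, NA_real_)
  new_pathway_fractions(times, frac(bb), frac(hb), frac(hc), total, "exact")
}

reachable_from <- function(flows, source) {
  seen <- source
  repeat {
    new <- setdiff(unique(flows$to[flows$from %in% seen]), seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  seen
}

#' Sample energy-quantum walkers on the network (Monte Carlo jump chain)
#'
#' Simulates the continuous-time Markov jump chain equivalent to the master
#' equation: each walker starts at `source`, waits at node `i` an exponential
#' time with rate `sum_j k_ij` (cooling included), jumps to `j` with
#' probability proportional to `k_ij`, and terminates at first sensor
#' arrival, solvent absorption, or `t_max`. Because the master equation is
#' linear, unit-energy walkers are an unbiased sampler of the energy flow.
#'
#' @param network an `energy_network`.
#' @param source,sensor node names (or residue numbers).
#' @param n_walkers number of walkers (>= 1).
#' @param t_max time horizon (ps).
#' @param seed RNG seed; runs are fully reproducible.
#' @param record_paths if `TRUE`, attach the full per-walker edge-class
#'   sequences as attribute `"paths"` (memory-heavy for large `n_walkers`).
#' @return data.frame with one row per walker: `outcome`
#'   (`"sensor"`/`"solvent"`/`"t_max"`), `arrival_time` (ps, `NA` unless
#'   arrived), `seen_hb`, `seen_hc` (logical), `class` (path class for
#'   arrivals), `n_jumps`.
#' @export
sample_jump_chain <- function(network, source, sensor, n_walkers, t_max = 50,
                              seed = 1, record_paths = FALSE) {
  if (is.numeric(source)) source <- res_node(source)
  if (is.numeric(sensor)) sensor <- res_node(sensor)
  stopifnot(source %in% network$nodes, sensor %in% network$nodes, n_walkers >= 1)
  fl <- directed_flows(network)
  nodes <- network$nodes
  ni <- setNames(seq_along(nodes), nodes)
  # guard: a reachable, non-absorbing node with no outgoing rate traps walkers
  out_rate <- tapply(fl$rate, factor(fl$from, levels = nodes), sum, default = 0)
  reach <- reachable_from(fl, source)
  dead <- setdiff(reach, c(sensor, SOLVENT_NODE))
  dead <- dead[out_rate[dead] == 0]
  if (length(dead) > 0L)
    stop(sprintf("node(s) with all-zero outgoing rates: %s",
                 paste(dead, collapse = ", ")))
  class_code <- match(fl$class, EDGE_CLASSES)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  res <- jump_chain_cpp(length(nodes), ni[fl$from] - 1L, ni[fl$to] - 1L,
                        fl$rate, class_code, ni[source] - 1L, ni[sensor] - 1L,
                        ni[SOLVENT_NODE] - 1L, as.integer(n_walkers), t_max,
                        isTRUE(record_paths))
  out <- data.frame(outcome = c("sensor", "solvent", "t_max")[res$outcome],
                    arrival_time = ifelse(res$outcome == 1L, res$time, NA_real_),
                    seen_hb = res$seen_hb > 0L, seen_hc = res$seen_hc > 0L,
                    n_jumps = res$n_jumps)
  out$class <- ifelse(out$outcome != "sensor", NA_character_,
                      ifelse(out$seen_hc, "HC", ifelse(out$seen_hb, "HB", "BB")))
  if (isTRUE(record_paths)) {
    attr(out, "edge_paths") <- res$paths  # 1-based indices into directed_flows()
    attr(out, "paths") <- lapply(res$paths, function(p) fl$class[p])
  }
  out
}

#' Monte Carlo pathway fractions from walker records
#'
#' Bins first-passage arrivals on the time grid and reports, at each time, the
#' cumulative per-class share of all walkers that have reached the sensor so
#' far.
#'
#' @param records data.frame from [sample_jump_chain()].
#' @param times time grid (ps).
#' @return A `pathway_fractions` object; `total_arrived` is the arrived
#'   fraction of all walkers. Fractions are `NA` before the first arrival; if
#'   no walker arrived at all the result carries attribute
#'   `"no_arrivals" = TRUE`.
#' @export
mc_pathway_fractions <- function(records, times = seq(0, 50, by = 0.05)) {
  arr <- records[records$outcome == "sensor", , drop = FALSE]
  n_tot <- nrow(records)
  cum_class <- function(cl) {
    tt <- sort(arr$arrival_time[arr$class == cl])
    vapply(times, function(t) sum(tt <= t), numeric(1))
  }
  bb <- cum_class("BB"); hb <- cum_class("HB"); hc <- cum_class("HC")
  total <- bb + hb + hc
  frac <- function(x) ifelse(total > 0, x / total, NA_real_)
  out <- new_pathway_fractions(times, frac(bb), frac(hb), frac(hc),
                               total / n_tot, "monte-carlo")
  if (nrow(arr) == 0L) {
    warning("no walker reached the sensor; fractions undefined")
    attr(out, "no_arrivals") <- TRUE
  }
  out
}

#' Pathway fractions at one time
#' @param fractions a `pathway_fractions`.
#' @param at time (ps); defaults to the last grid point.
#' @return named numeric vector `BB`, `HB`, `HC`, `total_arrived`.
#' @export
fractions_at <- function(fractions, at = NULL) {
  f <- fractions$fractions
  k <- if (is.null(at)) nrow(f) else which.min(abs(f$time - at))
  c(BB = f$BB[k], HB = f$HB[k], HC = f$HC[k], total_arrived = f$total_arrived[k])
}

#' Per-edge transit counts of sensor-arriving walkers
#'
#' Re-runs the jump chain recording, for walkers that reach the sensor, how
#' often each directed edge was traversed — the data behind pathway "arrow
#' diagram" renderings.
#'
#' @inheritParams sample_jump_chain
#' @return data.frame `from`, `to`, `class`, `count`, ordered by count.
#' @export
edge_flux_table <- function(network, source, sensor, n_walkers, t_max = 50,
                            seed = 1) {
  rec <- sample_jump_chain(network, source, sensor, n_walkers, t_max, seed,
                           record_paths = TRUE)
  fl <- directed_flows(network)
  idx <- unlist(attr(rec, "edge_paths")[rec$outcome == "sensor"])
  counts <- tabulate(idx, nbins = nrow(fl))
  agg <- data.frame(fl[, c("from", "to", "class")], count = counts)
  agg[order(-agg$count), ]
}

#' Write pathway fractions as CSV
#' @param fractions a `pathway_fractions`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fractions_csv <- function(fractions, file) {
  write.csv(fractions$fractions, file, row.names = FALSE)
  invisible(file)
}
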