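# Fixture networks built directly as energy_network objects, plus independent
# oracles used against the package's own solvers.

make_network <- function(edges, heater = 1L, extra_nodes = character()) {
  res <- sort(unique(as.integer(sub("^R", "", grep("^R\\d+$",
          unique(c(edges$i, edges$j)), value = TRUE)))))
  nodes <- unique(c(paste0("R", res), "HEATER_POOL", "SOLVENT", extra_nodes))
  n_dof <- setNames(rep(12, length(nodes)), nodes)
  n_dof["HEATER_POOL"] <- 39
  n_dof["SOLVENT"] <- NA_real_
  structure(list(nodes = nodes, edges = edges, n_dof = n_dof, heater = heater),
            class = "energy_network")
}

edge_df <- function(...) {
  m <- do.call(rbind, list(...))
  data.frame(i = m[, 1], j = m[, 2], class = m[, 3],
             rate = as.numeric(m[, 4]), stringsAsFactors = FALSE)
}

# heater pool -> R1 -> solvent
chain_network <- function(k_h = 1, k_s = 1 / 6) {
  make_network(edge_df(c("HEATER_POOL", "R1", "HEAT", k_h),
                       c("R1", "SOLVENT", "COOL", k_s)))
}

# two residues joined by one symmetric edge, no source/sink
two_node_network <- function(k = 0.5, class = "BB") {
  make_network(edge_df(c("R1", "R2", class, k)))
}

# parallel routes R1->R3: direct HB vs two-hop backbone, no sink
toy_parallel_network <- function(k_hb = 1, k_bb = 1) {
  make_network(edge_df(c("R1", "R3", "HB", k_hb),
                       c("R1", "R2", "BB", k_bb),
                       c("R2", "R3", "BB", k_bb)))
}

# 4-node diamond with a removable donor-sensor hydrogen bond and cooling
diamond_network <- function(k_hb = 0.5) {
  make_network(edge_df(c("HEATER_POOL", "R1", "HEAT", 1),
                       c("R1", "R2", "BB", 2),
                       c("R2", "R3", "BB", 2),
                       c("R3", "R4", "BB", 2),
                       c("R1", "R4", "HB", k_hb),
                       c("R1", "SOLVENT", "COOL", 0.1),
                       c("R2", "SOLVENT", "COOL", 0.1),
                       c("R3", "SOLVENT", "COOL", 0.1),
                       c("R4", "SOLVENT", "COOL", 0.1)))
}

# uniform backbone-only chain of n residues, no sink
bb_chain_network <- function(n, k = 1) {
  e <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    data.frame(i = paste0("R", i), j = paste0("R", i + 1), class = "BB",
               rate = k, stringsAsFactors = FALSE)))
  make_network(e)
}

# random connected symmetric network over n residues with heater and sink
random_symmetric_network <- function(n, seed, with_sink = TRUE) {
  set.seed(seed)
  rows <- lapply(2:n, function(i) {  # random spanning tree keeps it connected
    j <- sample(seq_len(i - 1), 1)
    data.frame(i = paste0("R", j), j = paste0("R", i),
               class = sample(c("BB", "HB", "HC"), 1),
               rate = runif(1, 0.1, 3), stringsAsFactors = FALSE)
  })
  n_extra <- sample(0:n, 1)
  for (k in seq_len(n_extra)) {
    ij <- sample(n, 2)
    rows[[length(rows) + 1]] <- data.frame(i = paste0("R", ij[1]),
                                           j = paste0("R", ij[2]),
                                           class = sample(c("BB", "HB", "HC"), 1),
                                           rate = runif(1, 0.1, 3),
                                           stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(i = "HEATER_POOL", j = "R1",
                                         class = "HEAT", rate = runif(1, 0.5, 2),
                                         stringsAsFactors = FALSE)
  if (with_sink)
    for (i in seq_len(n))
      rows[[length(rows) + 1]] <- data.frame(i = paste0("R", i), j = "SOLVENT",
                                             class = "COOL",
                                             rate = runif(1, 0.05, 0.3),
                                             stringsAsFactors = FALSE)
  make_network(do.call(rbind, rows))
}

# Independent oracle: pathway-class shares of the embedded discrete jump
# chain, by exact dynamic programming over (node, seen-HB, seen-HC) states to
# a fixed jump depth. Equivalent to exhaustive path enumeration with paths
# sharing a state merged; asymptotic (t -> infinity) class shares.
enum_pathway_shares <- function(network, source, sensor, depth = 25) {
  fl <- vetflow:::directed_flows(network)
  nodes <- network$nodes
  tot <- tapply(fl$rate, factor(fl$from, levels = nodes), sum, default = 0)
  # state: list over flag combos of named prob vectors; absorbed per class
  flags <- c("00", "10", "01", "11")
  p <- lapply(flags, function(f) setNames(numeric(length(nodes)), nodes))
  names(p) <- flags
  p[["00"]][source] <- 1
  arrived <- c(BB = 0, HB = 0, HC = 0)
  class_of <- c("00" = "BB", "10" = "HB", "01" = "HC", "11" = "HC")
  for (step in seq_len(depth)) {
    q <- lapply(flags, function(f) setNames(numeric(length(nodes)), nodes))
    names(q) <- flags
    for (f in flags) for (k in seq_len(nrow(fl))) {
      from <- fl$from[k]
      if (from == sensor || from == "SOLVENT") next
      mass <- p[[f]][from] * fl$rate[k] / tot[from]
      if (mass == 0) next
      f2 <- f
      if (fl$class[k] == "HB") f2 <- c("00" = "10", "10" = "10", "01" = "11", "11" = "11")[f]
      if (fl$class[k] == "HC") f2 <- c("00" = "01", "10" = "11", "01" = "01", "11" = "11")[f]
      to <- fl$to[k]
      if (to == sensor) arrived[class_of[f2]] <- arrived[class_of[f2]] + mass
      else q[[f2]][to] <- q[[f2]][to] + mass
    }
    p <- q
  }
  arrived / sum(arrived)
}

# residue-only view of a trajectory, as observed traces
residue_traces <- function(traj) {
  keep <- grep("^R\\d+$", traj$nodes, value = TRUE)
  structure(list(times = traj$times,
                 energies = traj$energies[, keep, drop = FALSE], nodes = keep),
            class = "energy_trajectory")
}

expect_within_3sigma <- function(mc, exact, n_arrivals) {
  for (cl in c("BB", "HB", "HC")) {
    p <- exact[[cl]]
    sig <- sqrt(max(p * (1 - p), 1e-12) / n_arrivals)
    expect_lt(abs(mc[[cl]] - p), 3 * sig + 1e-12)
  }
}
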