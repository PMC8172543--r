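#' @useDynLib vetflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize optim lm coef rnorm runif median setNames quantile
#' @importFrom utils write.csv read.csv
NULL

HEATER_NODE <- "HEATER_POOL"
SOLVENT_NODE <- "SOLVENT"
EDGE_CLASSES <- c("BB", "HB", "HC", "HEAT", "COOL")
INTRA_CLASSES <- c("BB", "HB", "HC")

res_node <- function(resno) paste0("R", resno)

# position of the amide hydrogen, inferred from backbone geometry: along the
# outward bisector of N->CA and N->C(i-1) (N->C of the same residue for the
# first residue, which has no preceding carbonyl).
infer_amide_h <- function(structure, resno) {
  N <- atom_coord(structure, resno, "N")
  CA <- atom_coord(structure, resno, "CA")
  resnos <- residue_numbers(structure)
  prev <- resnos[which(resnos == resno) - 1L]
  Cref <- if (length(prev) == 1L) atom_coord(structure, prev, "C")
          else atom_coord(structure, resno, "C")
  u1 <- (N - CA) / sqrt(sum((N - CA)^2))
  u2 <- (N - Cref) / sqrt(sum((N - Cref)^2))
  d <- u1 + u2
  nd <- sqrt(sum(d^2))
  if (nd < 1e-8) d <- u1 else d <- d / nd
  N + 1.01 * d
}

vec_angle_deg <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Detect backbone hydrogen bonds
#'
#' Scans all residue pairs with sequence separation `|i - j| >= 3` for a
#' backbone amide-to-carbonyl hydrogen bond in either direction: donor N to
#' acceptor O distance within `hb_cutoff` and N-H...O angle (at the inferred
#' amide hydrogen) of at least `hb_angle_min`. Each unordered pair is reported
#' once, with the shorter qualifying N...O distance.
#'
#' @param structure a [vet_structure].
#' @param hb_cutoff donor-acceptor N...O cutoff (A).
#' @param hb_angle_min minimum N-H...O angle (degrees).
#' @return data.frame with columns `i`, `j` (residue numbers, `i < j`) and
#'   `dist` (N...O distance, A); zero rows if no bonds.
#' @export
detect_hydrogen_bonds <- function(structure, hb_cutoff = 3.5, hb_angle_min = 120) {
  resnos <- residue_numbers(structure)
  out <- list()
  for (a in seq_along(resnos)) for (b in seq_along(resnos)) {
    if (a == b) next
    ri <- resnos[a]; rj <- resnos[b]
    if (abs(ri - rj) < 3) next
    if (ri > rj) next  # evaluate both donor directions below
    best <- Inf
    for (dir in 1:2) {
      don <- if (dir == 1) ri else rj
      acc <- if (dir == 1) rj else ri
      N <- atom_coord(structure, don, "N")
      O <- atom_coord(structure, acc, "O")
      if (is.null(N) || is.null(O)) next
      d <- sqrt(sum((N - O)^2))
      if (d > hb_cutoff) next
      H <- infer_amide_h(structure, don)
      ang <- vec_angle_deg(N - H, O - H)
      if (ang >= hb_angle_min) best <- min(best, d)
    }
    if (is.finite(best)) out[[length(out) + 1L]] <- data.frame(i = ri, j = rj, dist = best)
  }
  if (length(out) == 0L) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  do.call(rbind, out)
}

#' Detect heater side-chain contacts
#'
#' Finds residues whose heavy atoms approach any heater side-chain heavy atom
#' within `hc_cutoff`, at sequence separation `|heater - j| >= 3`. These model
#' the direct van der Waals / electrostatic coupling of the bulky photoexcited
#' side chain to the opposite strand; they may coexist with a hydrogen bond
#' between the same residue pair.
#'
#' @param structure a [vet_structure].
#' @param heater_index residue number of the heater (donor) residue.
#' @param hc_cutoff heavy-atom distance cutoff (A).
#' @return data.frame with columns `i` (heater), `j`, `dist` (minimum
#'   heavy-atom distance, A); zero rows if the heater has no side chain or no
#'   residue is within the cutoff.
#' @export
detect_heater_contacts <- function(structure, heater_index, hc_cutoff = 4.5) {
  resnos <- residue_numbers(structure)
  if (!(heater_index %in% resnos)) stop("invalid heater residue index")
  sc <- residue_coords(structure, heater_index, exclude_backbone = TRUE)
  out <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (nrow(sc) == 0L) return(out)
  for (rj in resnos) {
    if (abs(rj - heater_index) < 3) next
    xy <- residue_coords(structure, rj)
    d2 <- outer(rowSums(sc^2), rowSums(xy^2), "+") - 2 * sc %*% t(xy)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin <= hc_cutoff)
      out <- rbind(out, data.frame(i = heater_index, j = rj, dist = dmin))
  }
  out
}

#' Assemble the residue energy-transport network
#'
#' Builds the rate network on residues plus a heater pool source and a solvent
#' sink. Backbone (BB) edges connect sequence neighbours with
#' `k = D_B / d^2` (`d` = Calpha-Calpha distance); hydrogen-bond (HB) and
#' heater-contact (HC) edges carry `k = D_C / r^p`; a HEAT edge injects from
#' the heater pool into the heater residue at `k_h`; every residue cools into
#' the solvent at `k_s`. All intramolecular edges are symmetric.
#'
#' @param structure a [vet_structure].
#' @param hb_pairs data.frame from [detect_hydrogen_bonds()] (columns `i`,
#'   `j`, optionally `dist`; missing distances are recomputed as N...O).
#' @param hc_pairs data.frame from [detect_heater_contacts()].
#' @param params a [transport_params].
#' @param heater heater residue number; defaults to `hc_pairs$i[1]` when
#'   contacts are present.
#' @param heater_dof degrees of freedom of the heater pool (see
#'   [heater_spec()]).
#' @return An object of class `energy_network`: `nodes` (names), `edges`
#'   (data.frame `i`, `j`, `class`, `rate`), `n_dof` (named vector), `heater`
#'   (residue number).
#' @export
assemble_network <- function(structure, hb_pairs, hc_pairs, params,
                             heater = NULL, heater_dof = 39) {
  resnos <- residue_numbers(structure)
  if (is.null(heater)) {
    if (nrow(hc_pairs) > 0L) heater <- hc_pairs$i[1]
    else stop("heater residue must be given when no heater contacts are present")
  }
  if (!(heater %in% resnos)) stop("invalid heater residue index")
  p <- params
  edges <- list()
  add_edge <- function(i, j, class, rate)
    edges[[length(edges) + 1L]] <<- data.frame(i = i, j = j, class = class,
                                               rate = rate, stringsAsFactors = FALSE)
  # backbone: consecutive residues
  for (k in seq_len(length(resnos) - 1L)) {
    ri <- resnos[k]; rj <- resnos[k + 1L]
    d <- sqrt(sum((atom_coord(structure, ri, "CA") - atom_coord(structure, rj, "CA"))^2))
    if (d <= 0) stop(sprintf("zero Calpha distance between residues %d and %d", ri, rj))
    add_edge(res_node(ri), res_node(rj), "BB", p$D_B / d^2)
  }
  contact_edge <- function(pairs, class) {
    for (k in seq_len(nrow(pairs))) {
      ri <- pairs$i[k]; rj <- pairs$j[k]
      if (!(ri %in% resnos) || !(rj %in% resnos))
        stop("contact pair references an unknown residue")
      r <- if ("dist" %in% names(pairs)) pairs$dist[k] else NA_real_
      if (is.na(r)) {
        dNO <- sqrt(sum((atom_coord(structure, ri, "N") - atom_coord(structure, rj, "O"))^2))
        dON <- sqrt(sum((atom_coord(structure, ri, "O") - atom_coord(structure, rj, "N"))^2))
        r <- min(dNO, dON)
      }
      if (r <= 0) stop("zero contact distance")
      add_edge(res_node(ri), res_node(rj), class, p$D_C / r^p$contact_exponent)
    }
  }
  contact_edge(hb_pairs, "HB")
  contact_edge(hc_pairs, "HC")
  add_edge(HEATER_NODE, res_node(heater), "HEAT", p$k_h)
  for (ri in resnos) add_edge(res_node(ri), SOLVENT_NODE, "COOL", p$k_s)
  edges <- do.call(rbind, edges)
  n_dof <- c(setNames(vapply(resnos, function(r) 3 * nrow(residue_coords(structure, r)),
                             numeric(1)), res_node(resnos)),
             setNames(c(heater_dof, NA_real_), c(HEATER_NODE, SOLVENT_NODE)))
  net <- structure(list(nodes = c(res_node(resnos), HEATER_NODE, SOLVENT_NODE),
                        edges = edges, n_dof = n_dof, heater = heater),
                   class = "energy_network")
  comp <- reachable_residues(net)
  missing <- setdiff(setdiff(net$nodes, SOLVENT_NODE), comp)
  if (length(missing) > 0L)
    warning(sprintf("disconnected node(s): %s", paste(missing, collapse = ", ")))
  net
}

# nodes reachable from the heater pool along rate > 0 edges (intramolecular
# edges traversable both ways)
reachable_residues <- function(network) {
  e <- network$edges[network$edges$rate > 0 & network$edges$class != "COOL", , drop = FALSE]
  seen <- HEATER_NODE
  repeat {
    nxt <- unique(c(e$j[e$i %in% seen],
                    e$i[e$j %in% seen & e$class %in% INTRA_CLASSES]))
    new <- setdiff(nxt, seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  seen
}

#' @export
print.energy_network <- function(x, ...) {
  tab <- table(factor(x$edges$class, levels = EDGE_CLASSES))
  cat(sprintf("<energy_network> %d nodes (heater residue %d); edges: %s\n",
              length(x$nodes), x$heater,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " ")))
  invisible(x)
}

#' Apply the quantum correction to a network
#'
#' Multiplies all intramolecular (BB, HB, HC) and heater (HEAT) rates by the
#' factor `Q >= 1`. Cooling (COOL) rates are untouched: solvent dissipation is
#' slow compared to an intramolecular transfer step and essentially classical,
#' and is anyway taken from experiment.
#'
#' @param network an `energy_network`.
#' @param Q dimensionless factor, `>= 1`.
#' @return The corrected `energy_network`.
#' @export
apply_quantum_correction <- function(network, Q) {
  if (Q < 1) stop("quantum correction Q must be >= 1")
  sel <- network$edges$class %in% c(INTRA_CLASSES, "HEAT")
  network$edges$rate[sel] <- network$edges$rate[sel] * Q
  network
}

#' Prune contact edges (hydrogen bonds and heater contacts)
#'
#' Models partial unfolding (e.g. denaturant-ruptured interstrand hydrogen
#' bonds) by zeroing the rates of a random fraction of the HB/HC edges, or of
#' an explicitly listed set. Backbone and cooling edges are untouched.
#'
#' @param network an `energy_network`.
#' @param fraction fraction of contact edges to remove, in `[0, 1]`.
#' @param edges optional data.frame/matrix with columns `i`, `j` (node names)
#'   selecting specific contact edges; overrides `fraction`.
#' @param seed RNG seed making the random selection reproducible.
#' @return The pruned `energy_network` (removed edges kept with rate 0).
#' @export
prune_contacts <- function(network, fraction = 0, edges = NULL, seed = 1) {
  idx <- which(network$edges$class %in% c("HB", "HC"))
  if (!is.null(edges)) {
    key <- paste(network$edges$i, network$edges$j)
    key2 <- paste(network$edges$j, network$edges$i)
    want <- paste(edges[, "i"], edges[, "j"])
    kill <- idx[key[idx] %in% want | key2[idx] %in% want]
  } else {
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
    n_kill <- round(fraction * length(idx))
    kill <- if (n_kill == 0L) integer() else {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      idx[sample.int(length(idx), n_kill)]
    }
  }
  network$edges$rate[kill] <- 0
  network
}

#' Write a network to JSON
#' @param network an `energy_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network_json <- function(network, file) {
  jsonlite::write_json(list(nodes = network$nodes, heater = network$heater,
                            n_dof = as.list(network$n_dof),
                            edges = network$edges),
                       file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' Read a network from JSON
#' @param file path written by [write_network_json()].
#' @return An `energy_network`.
#' @export
read_network_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(nodes = x$nodes, edges = as.data.frame(x$edges),
                 n_dof = unlist(x$n_dof), heater = x$heater),
            class = "energy_network")
}

#' Write the edge table as CSV
#' @param network an `energy_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_edge_table <- function(network, file) {
  write.csv(network$edges, file, row.names = FALSE)
  invisible(file)
}
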