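#' Variant specification: donor and sensor placement
#'
#' @param name variant name (e.g. `"V1"`).
#' @param donor donor (heater) residue position, 1-based.
#' @param sensor sensor residue position, 1-based.
#' @param strand `"same"` or `"opposite"`: whether donor and sensor sit on
#'   the same beta-strand.
#' @param n_res chain length the positions refer to.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(name, donor, sensor, strand = c("opposite", "same"),
                         n_res = 12) {
  strand <- match.arg(strand)
  if (donor == sensor) stop("donor and sensor must differ")
  if (donor < 1 || donor > n_res || sensor < 1 || sensor > n_res)
    stop("donor/sensor positions outside the chain")
  structure(list(name = name, donor = donor, sensor = sensor,
                 strand = strand, n_res = n_res),
            class = "variant_spec")
}

#' The four hairpin variants
#'
#' Donor/sensor placements of the four studied hairpin variants on a
#' 12-residue scaffold. V1 (donor 1, sensor 12, opposite strands) and V4
#' (donor 1, sensor 5, same strand) are fixed by the experimental design;
#' the V2/V3 sensor positions (10 and 8, opposite strand, backbone
#' separations between V1's and V4's) are assumptions of this package — the
#' original positions are not stated numerically in running text.
#'
#' @return named list of [variant_spec] objects `V1`..`V4`.
#' @export
make_variants <- function() {
  list(V1 = variant_spec("V1", 1, 12, "opposite"),
       V2 = variant_spec("V2", 1, 10, "opposite"),
       V3 = variant_spec("V3", 1, 8, "opposite"),
       V4 = variant_spec("V4", 1, 5, "same"))
}

#' Idealized antiparallel beta-hairpin structure
#'
#' Builds a deterministic, flat idealized two-strand antiparallel hairpin:
#' Calpha spacing 3.5 A along each strand, strands 5 A apart, residue `i`
#' registered against residue `n_res + 1 - i`, and backbone geometry arranged
#' so that cross-strand amide-carbonyl N...O distances are 3.0 A with
#' near-linear N-H...O angles — i.e. the hydrogen-bond ladder of a beta-sheet
#' as seen by [detect_hydrogen_bonds()]. The donor residue receives two dummy
#' side-chain heavy atoms (CB, CG) reaching toward the opposite strand so
#' heater contacts are detectable; all other residues are glycine-like
#' backbones. The geometry emulates a tryptophan-zipper-like scaffold without
#' requiring any structure download; real PDB structures enter through the
#' same [vet_structure] type.
#'
#' @param n_res even chain length >= 6.
#' @param turn_at last residue of the first strand; only the midpoint
#'   (`n_res / 2`, the default) is supported.
#' @param variant optional [variant_spec]; names the donor/sensor residues
#'   (`AZU`/`AHA`) and places the donor side chain. Defaults to donor 1.
#' @return A [vet_structure].
#' @export
make_idealized_hairpin <- function(n_res = 12, turn_at = n_res / 2,
                                   variant = NULL) {
  if (n_res %% 2 != 0 || n_res < 6) stop("n_res must be even and >= 6")
  if (turn_at != n_res / 2) stop("turn placement is fixed to the chain midpoint")
  donor <- if (is.null(variant)) 1L else variant$donor
  sensor <- if (is.null(variant)) NA_integer_ else variant$sensor
  h <- n_res / 2
  rows <- list()
  add <- function(resno, resid, elety, elesy, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(resno = resno, resid = resid,
                                             elety = elety, elesy = elesy,
                                             x = xyz[1], y = xyz[2], z = xyz[3],
                                             stringsAsFactors = FALSE)
  resid_of <- function(i) {
    if (i == donor) "AZU" else if (!is.na(sensor) && i == sensor) "AHA" else "GLY"
  }
  for (i in seq_len(n_res)) {
    on_first <- i <= h
    x <- if (on_first) 3.5 * (i - 1) else 3.5 * (n_res - i)
    yb <- if (on_first) 0 else 5.0
    s <- if (on_first) 1 else -1  # strand direction along x; flips N/C sides
    rid <- resid_of(i)
    add(i, rid, "N",  "N", c(x - s * 1.2, yb + s * 0.5, 0))
    add(i, rid, "CA", "C", c(x, yb, 0))
    add(i, rid, "C",  "C", c(x + s * 1.2, yb + s * 0.5, 0))
    add(i, rid, "O",  "O", c(x + s * 1.2, yb + s * 1.5, 0))
    if (i == donor) {  # dummy side chain reaching toward the other strand
      ca <- c(x, yb, 0)
      toward <- if (on_first) 1 else -1
      add(i, rid, "CB", "C", ca + c(0.0, toward * 1.3, 1.5))
      add(i, rid, "CG", "C", ca + c(0.2, toward * 2.0, 2.5))
    }
  }
  vet_structure(do.call(rbind, rows), chain = "A")
}

#' Ensemble specification for MD-like noisy traces
#'
#' Describes the emulated non-equilibrium ensemble: number of trajectories
#' averaged, trace length, and the heater jump. The ensemble average of
#' `n_traj` independent trajectories carries Gaussian noise on each grid
#' point with standard deviation `E_scale / sqrt(n_traj)` (central-limit
#' scaling), vanishing as the ensemble grows.
#'
#' @param n_traj number of averaged trajectories (default 5000).
#' @param t_max trace length (ps, default 50).
#' @param dt grid spacing (ps).
#' @param E_scale per-trajectory energy fluctuation scale, in units of the
#'   injected quantum.
#' @param heater a [heater_spec] defining the temperature jump.
#' @param seed RNG seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_traj = 5000, t_max = 50, dt = 0.05, E_scale = 1,
                          heater = heater_spec(), seed = 1) {
  if (n_traj < 1) stop("n_traj must be >= 1")
  structure(list(n_traj = n_traj, t_max = t_max, dt = dt, E_scale = E_scale,
                 heater = heater, sigma = E_scale / sqrt(n_traj), seed = seed),
            class = "ensemble_spec")
}

#' Simulate a noisy MD-like residue-energy ensemble
#'
#' Integrates the master equation on the network (ground truth) and adds
#' i.i.d. Gaussian noise of standard deviation `E_scale / sqrt(n_traj)` to
#' the residue traces, emulating the ensemble average of `n_traj`
#' non-equilibrium trajectories after the heater temperature jump.
#'
#' @param network an `energy_network` (the hidden truth generator).
#' @param spec an [ensemble_spec].
#' @return list with `observed` (residue-only `energy_trajectory` with
#'   noise), `truth` (full noise-free trajectory) and `sigma` (noise sd).
#' @export
simulate_noisy_ensemble <- function(network, spec = ensemble_spec()) {
  times <- seq(0, spec$t_max, by = spec$dt)
  truth <- integrate_master_equation(network, times = times)
  res_nodes <- grep("^R\\d+$", truth$nodes, value = TRUE)
  Y <- truth$energies[, res_nodes, drop = FALSE]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  noisy <- Y + matrix(rnorm(length(Y), sd = spec$sigma), nrow(Y), ncol(Y))
  observed <- structure(list(times = times, energies = noisy, nodes = res_nodes),
                        class = "energy_trajectory")
  list(observed = observed, truth = truth, sigma = spec$sigma)
}

#' Build the full network of a variant on the idealized hairpin
#'
#' Convenience wrapper: idealized structure for the variant, hydrogen-bond
#' and heater-contact detection, network assembly.
#'
#' @param variant a [variant_spec].
#' @param params a [transport_params].
#' @param n_res chain length.
#' @return list with `structure`, `template` (a [network_template]) and
#'   `network` (`energy_network`).
#' @export
build_variant_network <- function(variant, params = transport_params(),
                                  n_res = 12) {
  s <- make_idealized_hairpin(n_res = n_res, variant = variant)
  tmpl <- network_template(s, variant$donor, params)
  list(structure = s, template = tmpl, network = template_network(tmpl))
}
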