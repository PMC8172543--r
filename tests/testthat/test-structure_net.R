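test_that("structures round-trip through PDB text", {
  gg <- data.frame(resno = rep(1:2, each = 4),
                   resid = "GLY",
                   elety = rep(c("N", "CA", "C", "O"), 2),
                   elesy = rep(c("N", "C", "C", "O"), 2),
                   x = c(0, 1.2, 2.1, 2.1, 3.5, 4.7, 5.6, 5.6),
                   y = c(0.5, 0, 0.5, 1.5, 0.5, 0, 0.5, 1.5),
                   z = 0)
  s <- vet_structure(gg)
  s2 <- parse_pdb(write_pdb(s))
  expect_equal(n_residues(s2), 2L)
  expect_equal(s2$atoms$elety, s$atoms$elety)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-6)

  h <- make_idealized_hairpin(12, variant = make_variants()$V1)
  h2 <- parse_pdb(write_pdb(h))
  expect_equal(h2$atoms$resno, h$atoms$resno)
  expect_equal(h2$atoms$elety, h$atoms$elety)
  expect_equal(as.matrix(h2$atoms[, c("x", "y", "z")]),
               as.matrix(h$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-6)

  expect_error(parse_pdb(""), "empty")
  noN <- gg[gg$elety != "N" | gg$resno != 2, ]
  expect_error(vet_structure(noN), "missing backbone atom N in residue 2")
})

test_that("hydrogen-bond detection matches a brute-force geometric scan", {
  s <- make_idealized_hairpin(12, variant = make_variants()$V1)
  got <- detect_hydrogen_bonds(s)
  # independent scan: all residue pairs, both donor directions, raw geometry
  brute <- list()
  for (i in 1:11) for (j in (i + 1):12) {
    if (j - i < 3) next
    ok <- FALSE
    for (d in list(c(i, j), c(j, i))) {
      N <- vetflow:::atom_coord(s, d[1], "N")
      O <- vetflow:::atom_coord(s, d[2], "O")
      H <- vetflow:::infer_amide_h(s, d[1])
      dist <- sqrt(sum((N - O)^2))
      ang <- vetflow:::vec_angle_deg(N - H, O - H)
      if (dist <= 3.5 && ang >= 120) ok <- TRUE
    }
    if (ok) brute[[length(brute) + 1]] <- c(i, j)
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(got), nrow(brute))
  expect_equal(got[, c("i", "j")], as.data.frame(brute) |> setNames(c("i", "j")),
               ignore_attr = TRUE)
  # the cross-strand ladder: terminal pair present, no short-range pairs
  expect_true(any(got$i == 1 & got$j == 12))
  expect_true(all(abs(got$i - got$j) >= 3))

  # stretched structure: no contacts at all
  far <- s
  far$atoms$x <- far$atoms$x + 100 * far$atoms$resno
  far <- vet_structure(far$atoms)
  expect_equal(nrow(detect_hydrogen_bonds(far)), 0L)
})

test_that("heater-contact detection respects side chains and cutoffs", {
  s <- make_idealized_hairpin(12, variant = make_variants()$V1)
  hc <- detect_heater_contacts(s, 1)
  expect_true(12 %in% hc$j)          # donor touches the opposite terminus
  expect_true(all(abs(hc$j - 1) >= 3))
  expect_equal(nrow(detect_heater_contacts(s, 1, hc_cutoff = 0.1)), 0L)
  # heater stripped to backbone: nothing to contact with
  bare <- vet_structure(s$atoms[!(s$atoms$elety %in% c("CB", "CG")), ])
  expect_equal(nrow(detect_heater_contacts(bare, 1)), 0L)
  expect_error(detect_heater_contacts(s, 99), "invalid heater")
})

test_that("assembled rates follow the inverse-square scaling rules", {
  at <- data.frame(resno = rep(1:3, each = 4), resid = "GLY",
                   elety = rep(c("N", "CA", "C", "O"), 3),
                   elesy = rep(c("N", "C", "C", "O"), 3),
                   x = rep(c(-1.2, 0, 1.2, 1.2), 3) + rep(3.8 * (0:2), each = 4),
                   y = rep(c(0.5, 0, 0.5, 1.5), 3), z = 0)
  s <- vet_structure(at)
  p <- transport_params(D_B = 8.66, D_C = 9.0)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  net <- assemble_network(s, empty, empty, p, heater = 1)
  bb <- net$edges[net$edges$class == "BB", ]
  expect_equal(bb$rate, rep(8.66 / 3.8^2, 2), tolerance = 1e-12)
  expect_equal(bb$rate[1], 0.5997, tolerance = 1e-4)

  hb <- data.frame(i = 1, j = 3, dist = 3.0)
  net2 <- assemble_network(s, hb, empty, p, heater = 1)
  expect_equal(net2$edges$rate[net2$edges$class == "HB"], 9.0 / 9.0)

  # D_C = 0: contact edges exist with rate 0 and dynamics equal the BB-only net
  p0 <- transport_params(D_B = 8.66, D_C = 0)
  net3 <- assemble_network(s, hb, empty, p0, heater = 1)
  expect_equal(net3$edges$rate[net3$edges$class == "HB"], 0)
  t1 <- integrate_master_equation(net3, times = seq(0, 10, 0.1))
  t2 <- integrate_master_equation(net2, times = seq(0, 10, 0.1))
  expect_false(isTRUE(all.equal(t1$energies, t2$energies)))  # contacts matter
  net_bb <- assemble_network(s, empty, empty, p0, heater = 1)
  t3 <- integrate_master_equation(net_bb, times = seq(0, 10, 0.1))
  expect_equal(t1$energies[, t3$nodes], t3$energies, tolerance = 1e-12)

  # degenerate geometry is a hard error
  bad <- at; bad$x <- 0; bad$y <- rep(c(0.5, 0, 0.5, 1.5), 3); bad$z <- 0
  expect_error(assemble_network(vet_structure(bad), empty, empty, p, heater = 1),
               "zero Calpha distance")
})

test_that("quantum correction scales intramolecular and heater rates only", {
  s <- make_idealized_hairpin(12, variant = make_variants()$V1)
  p <- transport_params()
  net <- assemble_network(s, detect_hydrogen_bonds(s),
                          detect_heater_contacts(s, 1), p, heater = 1)
  expect_equal(apply_quantum_correction(net, 1), net)
  q <- apply_quantum_correction(net, 3.1)
  intra <- net$edges$class %in% c("BB", "HB", "HC", "HEAT")
  expect_equal(q$edges$rate[intra], 3.1 * net$edges$rate[intra])
  expect_equal(q$edges$rate[!intra], net$edges$rate[!intra])
  expect_error(apply_quantum_correction(net, 0.9), "Q must be >= 1")

  # commutes with assembly: scaling D_B, D_C, k_h by Q gives the same network
  p_q <- transport_params(D_B = p$D_B * 3.1, D_C = p$D_C * 3.1, k_h = p$k_h * 3.1)
  net_q <- assemble_network(s, detect_hydrogen_bonds(s),
                            detect_heater_contacts(s, 1), p_q, heater = 1)
  expect_equal(q$edges$rate, net_q$edges$rate, tolerance = 1e-12)
})

test_that("rate symmetry and scaling homogeneity hold", {
  s <- make_idealized_hairpin(12, variant = make_variants()$V1)
  for (c_fac in c(0.5, 2, 7)) {
    p1 <- transport_params()
    p2 <- transport_params(D_B = p1$D_B * c_fac, D_C = p1$D_C * c_fac)
    n1 <- assemble_network(s, detect_hydrogen_bonds(s),
                           detect_heater_contacts(s, 1), p1, heater = 1)
    n2 <- assemble_network(s, detect_hydrogen_bonds(s),
                           detect_heater_contacts(s, 1), p2, heater = 1)
    intra <- n1$edges$class %in% c("BB", "HB", "HC")
    expect_equal(n2$edges$rate[intra], c_fac * n1$edges$rate[intra])
    expect_equal(n2$edges$rate[!intra], n1$edges$rate[!intra])
    # generator symmetry between residues
    A <- generator_matrix(n1)
    res <- grep("^R", colnames(A), value = TRUE)
    expect_equal(A[res, res] - diag(diag(A[res, res])),
                 t(A[res, res] - diag(diag(A[res, res]))), tolerance = 1e-12)
  }
})

test_that("contact pruning removes only contact channels, reproducibly", {
  b <- build_variant_network(make_variants()$V1)
  net <- b$network
  expect_equal(prune_contacts(net, fraction = 0), net)
  full <- prune_contacts(net, fraction = 1)
  expect_true(all(full$edges$rate[full$edges$class %in% c("HB", "HC")] == 0))
  expect_equal(full$edges$rate[full$edges$class %in% c("BB", "COOL")],
               net$edges$rate[net$edges$class %in% c("BB", "COOL")])
  # sensor on the opposite strand peaks later without contacts
  pk0 <- refine_peak_time(net, "R12")$peak_time
  pk1 <- refine_peak_time(full, "R12")$peak_time
  expect_gt(pk1, pk0)
  # explicit removal of the donor-sensor hydrogen bond in the diamond
  d <- diamond_network()
  d2 <- prune_contacts(d, edges = data.frame(i = "R1", j = "R4"))
  expect_equal(sum(d2$edges$rate[d2$edges$class == "HB"]), 0)
  expect_gt(refine_peak_time(d2, "R4")$peak_time,
            refine_peak_time(d, "R4")$peak_time)
  # seeded selection is reproducible
  expect_equal(prune_contacts(net, 0.5, seed = 42),
               prune_contacts(net, 0.5, seed = 42))
})

test_that("heater specification reproduces the ~600 K jump", {
  h <- heater_spec()
  expect_lt(abs(h$delta_T - 600) / 600, 0.1)
  expect_equal(h$delta_T, 2 / (8.617333262e-5 * 39))
  expect_error(heater_spec(E_exc = -1), "delta_T")
})

test_that("network JSON and edge-table round trips preserve the network", {
  b <- build_variant_network(make_variants()$V1)
  f <- tempfile(fileext = ".json")
  write_network_json(b$network, f)
  back <- read_network_json(f)
  expect_equal(back$edges$rate, b$network$edges$rate)
  expect_equal(back$nodes, b$network$nodes)
  expect_equal(generator_matrix(back), generator_matrix(b$network))
  csv <- tempfile(fileext = ".csv")
  write_edge_table(b$network, csv)
  expect_equal(read.csv(csv)$rate, b$network$edges$rate)
})
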