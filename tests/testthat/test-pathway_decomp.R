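test_that("path classification follows the HC > HB > BB precedence", {
  expect_equal(classify_path(c("BB", "BB", "BB")), "BB")
  expect_equal(classify_path(c("BB", "HB", "BB")), "HB")
  expect_equal(classify_path(c("HC", "HB")), "HC")
  expect_equal(classify_path(c("HEAT", "BB", "COOL")), "BB")
  expect_error(classify_path(c("BB", "XX")), "unknown edge class")
})

test_that("a backbone-only chain yields BB fraction 1 at all times", {
  net <- bb_chain_network(5, k = 1)
  fr <- exact_pathway_fractions(net, "R1", "R5", times = seq(0, 30, 0.5))
  f <- fr$fractions
  arrived <- f$total_arrived > 0
  expect_true(all(f$BB[arrived] == 1))
  expect_true(all(f$HB[arrived] == 0 & f$HC[arrived] == 0))
})

test_that("exact fractions match exhaustive jump-chain enumeration on toys", {
  toy <- toy_parallel_network()
  ex <- fractions_at(exact_pathway_fractions(toy, "R1", "R3",
                                             times = seq(0, 80, 0.5)))
  en <- enum_pathway_shares(toy, "R1", "R3", depth = 25)
  expect_equal(unname(ex["BB"]), unname(en["BB"]), tolerance = 1e-6)
  expect_equal(unname(ex["HB"]), unname(en["HB"]), tolerance = 1e-6)

  # 5-node toy mixing all three classes and a sink
  toy5 <- make_network(edge_df(c("R1", "R2", "BB", 1.5),
                               c("R2", "R3", "BB", 1.5),
                               c("R3", "R4", "BB", 1.5),
                               c("R4", "R5", "BB", 1.5),
                               c("R1", "R5", "HB", 0.4),
                               c("R1", "R4", "HC", 0.3),
                               c("R2", "R5", "HB", 0.2),
                               c("R1", "SOLVENT", "COOL", 0.05),
                               c("R2", "SOLVENT", "COOL", 0.05),
                               c("R3", "SOLVENT", "COOL", 0.05),
                               c("R4", "SOLVENT", "COOL", 0.05)))
  ex5 <- fractions_at(exact_pathway_fractions(toy5, "R1", "R5",
                                              times = seq(0, 150, 0.5)))
  en5 <- enum_pathway_shares(toy5, "R1", "R5", depth = 400)
  for (cl in c("BB", "HB", "HC"))
    expect_equal(unname(ex5[cl]), unname(en5[cl]), tolerance = 1e-6)
})

test_that("expanded-system arrival equals the plain absorbing-chain arrival", {
  for (fixture in list(toy_parallel_network(), diamond_network())) {
    sensor <- if ("R4" %in% fixture$nodes) "R4" else "R3"
    source <- "R1"
    times <- seq(0, 40, 0.5)
    fr <- exact_pathway_fractions(fixture, source, sensor, times = times)
    # independent route: make the sensor absorbing in the plain network
    A <- generator_matrix(fixture)
    A[, sensor] <- 0
    e0 <- setNames(numeric(ncol(A)), colnames(A)); e0[source] <- 1
    plain <- integrate_master_equation(A, initial = e0, times = times)
    expect_equal(fr$fractions$total_arrived, plain$energies[, sensor],
                 tolerance = 1e-9)
  }
})

test_that("jump-chain sampling is exact in law and reproducible", {
  # degenerate: source equals sensor
  net <- two_node_network(k = 1)
  rec0 <- sample_jump_chain(net, "R1", "R1", 100, seed = 1, record_paths = TRUE)
  expect_true(all(rec0$outcome == "sensor"))
  expect_true(all(rec0$arrival_time == 0))
  expect_true(all(lengths(attr(rec0, "paths")) == 0))

  # two-node first passage is exponential
  rec <- sample_jump_chain(net, "R1", "R2", 1e5, t_max = 50, seed = 2)
  arr <- rec$arrival_time[rec$outcome == "sensor"]
  ks <- suppressWarnings(stats::ks.test(arr, stats::pexp, rate = 1))
  expect_lt(unname(ks$statistic), 0.01)

  # bit-identical reruns under the same seed
  r1 <- sample_jump_chain(net, "R1", "R2", 1000, seed = 7)
  r2 <- sample_jump_chain(net, "R1", "R2", 1000, seed = 7)
  expect_identical(r1, r2)

  # a reachable node with no outgoing rate would trap walkers: hard error
  dead <- make_network(edge_df(c("HEATER_POOL", "R1", "HEAT", 1),
                               c("R2", "R3", "BB", 1)))
  expect_error(sample_jump_chain(dead, "HEATER_POOL", "R3", 10, seed = 1),
               "all-zero outgoing rates")
})

test_that("Monte Carlo fractions agree with the exact decomposition", {
  toy <- toy_parallel_network()
  times <- seq(0, 80, 0.5)
  ex <- fractions_at(exact_pathway_fractions(toy, "R1", "R3", times = times))
  rec <- sample_jump_chain(toy, "R1", "R3", 1e5, t_max = 80, seed = 11)
  mc <- fractions_at(mc_pathway_fractions(rec, times = times))
  expect_within_3sigma(mc, ex, sum(rec$outcome == "sensor"))

  # MC classification from recorded paths equals the flag-based classes
  rec_p <- sample_jump_chain(toy, "R1", "R3", 2000, t_max = 80, seed = 3,
                             record_paths = TRUE)
  paths <- attr(rec_p, "paths")
  arrived <- which(rec_p$outcome == "sensor")
  replayed <- vapply(paths[arrived], classify_path, character(1))
  expect_equal(replayed, rec_p$class[arrived])

  # all-BB records give BB fraction 1
  chain <- bb_chain_network(4, k = 1)
  recb <- sample_jump_chain(chain, "R1", "R4", 5000, t_max = 100, seed = 5)
  frb <- fractions_at(mc_pathway_fractions(recb, times = seq(0, 100, 1)))
  expect_equal(unname(frb["BB"]), 1)

  # zero arrivals are flagged, not silently zero
  iso <- make_network(edge_df(c("R1", "SOLVENT", "COOL", 5),
                              c("R1", "R2", "BB", 1e-9)))
  expect_warning(
    out <- mc_pathway_fractions(sample_jump_chain(iso, "R1", "R2", 50,
                                                  t_max = 1, seed = 1),
                                times = seq(0, 1, 0.5)),
    "no walker")
  expect_true(isTRUE(attr(out, "no_arrivals")))
})

test_that("class shares respond monotonically to the donor-sensor HB rate", {
  shares <- vapply(c(0.2, 0.5, 1, 2, 4), function(k) {
    d <- diamond_network(k_hb = k)
    fractions_at(exact_pathway_fractions(d, "R1", "R4",
                                         times = seq(0, 50, 0.5)))["HB"]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  # and zeroing all contacts forces BB share 1
  d0 <- prune_contacts(diamond_network(), fraction = 1)
  f0 <- fractions_at(exact_pathway_fractions(d0, "R1", "R4",
                                             times = seq(0, 50, 0.5)))
  expect_equal(unname(f0["BB"]), 1)
})

test_that("Monte Carlo standard error shrinks with the walker count", {
  toy <- toy_parallel_network()
  times <- seq(0, 60, 1)
  hb_share <- function(n, seed) {
    rec <- sample_jump_chain(toy, "R1", "R3", n, t_max = 60, seed = seed)
    fractions_at(mc_pathway_fractions(rec, times = times))["HB"]
  }
  small <- vapply(1:40, function(s) hb_share(1000, 100 + s), numeric(1))
  big <- vapply(1:40, function(s) hb_share(4000, 200 + s), numeric(1))
  ratio <- sd(small) / sd(big)   # quadrupling the walkers should halve the SE
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("edge flux concentrates on the dominant route", {
  d <- diamond_network(k_hb = 5)   # strong shortcut dominates
  flux <- edge_flux_table(d, "R1", "R4", 5000, t_max = 50, seed = 9)
  expect_equal(flux$class[1], "HB")
  expect_true(all(flux$count >= 0))
})
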