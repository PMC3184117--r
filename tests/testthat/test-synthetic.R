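test_that("expected Ct follows the log-linear amplification model", {
  p <- simulator_params()
  expect_equal(expected_ct(1e6, p), 20)
  # four-fold more template: two cycles earlier
  expect_equal(expected_ct(4e6, p), 18)
  expect_equal(expected_ct(1e5, p), 20 + log2(10))
  # pre-amplification is a pure downward offset
  p2 <- simulator_params(preamp_cycles = 12)
  expect_equal(expected_ct(1e6, p2), 8)
  # efficiency below 1 stretches the cycles per decade
  p3 <- simulator_params(efficiency = 0.9)
  expect_equal(expected_ct(1e5, p3), 20 + log(10) / log(1.9))
  expect_error(expected_ct(0, p), "positive")
})

test_that("effective template adds mismatch-weighted cross-reaction", {
  cat_ <- assay_catalog(c("a1", "a2"), "p", c("m1", "m2"),
                        c("ACGTACGTACGTACGTACGTAC",
                          "TTGGCCAATTGGCCAATTGGCC"))
  des <- spike_design(c("S", "S"), c("m1", "hom"), c(2000, 1e6))
  hom <- data.frame(assay_id = "a2", platform_id = "p",
                    mirna_id = "hom", mismatches = 2L,
                    overhang_left = 0L, overhang_right = 0L,
                    aligned_length = 22L)
  p <- simulator_params(crossreact_base_fraction = 0.5,
                        crossreact_log10_penalty_per_mismatch = 1)
  eff <- effective_template(c("a1", "a2"), "S", cat_, des, hom, p)
  # no homologs: just the target's own copies
  expect_equal(unname(eff["a1"]), 2000)
  # absent target with a 2-mismatch homolog at 1e6: 1e6 * 0.5 * 10^-2
  expect_equal(unname(eff["a2"]), 5e3)
  # a prohibitive penalty removes cross-reaction entirely
  p_inf <- simulator_params(crossreact_base_fraction = 0.5,
                            crossreact_log10_penalty_per_mismatch = 400)
  eff2 <- effective_template(c("a1", "a2"), "S", cat_, des, hom, p_inf)
  expect_equal(unname(eff2["a2"]), 0)
  p_off <- simulator_params(crossreact_base_fraction = 0)
  expect_equal(unname(effective_template("a2", "S", cat_, des, hom,
                                         p_off)), 0)
})

test_that("simulation is reproducible bit for bit per seed", {
  sc <- small_scaffold()
  pl <- sc$platforms$mircury_like
  t1 <- simulate_ct_table(sc$design, pl$catalog, pl$homology,
                          pl$profile$params, seed = 123)
  t2 <- simulate_ct_table(sc$design, pl$catalog, pl$homology,
                          pl$profile$params, seed = 123)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- simulate_ct_table(sc$design, pl$catalog, pl$homology,
                          pl$profile$params, seed = 124)
  expect_false(identical(t1$ct, t3$ct))
})

test_that("poisson occupancy reproduces the closed-form detection rate", {
  n <- 1000L
  ids <- sprintf("m%04d", seq_len(n))
  panel <- mirna_panel(ids, replicate(n, {
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  }), rep(c("A", "B"), length.out = n))
  cat_ <- assay_catalog(paste0("a-", ids), "p", ids, panel$sequence)
  des <- spike_design(rep("S", n), ids, rep(0.5, n))
  hom <- build_homology_map(cat_[1, ], panel[1, , drop = FALSE])[0, ]
  # reference Ct low enough that single molecules stay in-run
  params <- simulator_params(ct_at_ref = 15, background_rate = 0,
                             crossreact_base_fraction = 0)
  set.seed(55)
  ct <- simulate_ct_table(des, cat_, hom, params, n_replicates = 1L,
                          samples = "S", seed = 55)
  frac <- mean(!is.na(ct$ct))
  expected <- 1 - exp(-0.5)
  tol <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), tol)
})

test_that("no-RT background fires at the configured rate", {
  sc <- small_scaffold()
  pl <- sc$platforms$mircury_like
  rate <- pl$profile$params$background_rate
  fracs <- numeric(10)
  for (i in 1:10) {
    st <- simulate_study(sc, seed = 500 + i)
    no_rt <- st$tables$mircury_like
    no_rt <- no_rt[no_rt$sample_id == "no_rt", ]
    fracs[i] <- mean(!is.na(no_rt$ct))
  }
  n_wells <- sum(st$tables$mircury_like$sample_id == "no_rt") * 10
  tol <- 3 * sqrt(rate * (1 - rate) / n_wells)
  expect_lt(abs(mean(fracs) - rate), tol)
  # background signals live in the configured late-Ct window
  vals <- st$tables$mircury_like
  vals <- vals$ct[vals$sample_id == "no_rt"]
  expect_true(all(is.na(vals) |
                    (vals >= pl$profile$params$background_ct_range[1] &
                       vals <= pl$profile$params$background_ct_range[2])))
})

test_that("study design encodes the reciprocal four-fold spike plan", {
  panel <- make_panel(8, 6, seed = 61)
  des <- study_design(panel)
  for (m in panel$mirna_id[panel$pool == "B"]) {
    expect_equal(expected_delta_ct(des$design, "synthetic_1",
                                   "synthetic_2", m), 2)
  }
  for (m in panel$mirna_id[panel$pool == "A"]) {
    expect_equal(expected_delta_ct(des$design, "synthetic_1",
                                   "synthetic_2", m), -2)
  }
  # five 10-fold points: the last is 1e4 below the first
  pts <- des$dilution_points
  expect_equal(nrow(pts), 5L)
  expect_equal(pts$copies_per_pcr[1L], 5000)
  expect_equal(pts$copies_per_pcr[5L], pts$copies_per_pcr[1L] / 1e4)
  expect_equal(pts$copies_per_pcr[5L], 0.5)
  # dilution samples scale the spiked-plasma design by the same factor
  d1 <- spikeval:::design_copies(des$design, "dil_1",
                                 panel$mirna_id[1L])
  d5 <- spikeval:::design_copies(des$design, "dil_5",
                                 panel$mirna_id[1L])
  expect_equal(unname(d1 / d5), 1e4)
})

test_that("a noiseless study recovers every design quantity exactly", {
  panel <- make_panel(10, 10, seed = 71)
  off <- make_offpanel(panel, n_random = 10, homolog_counts = integer(0),
                       seed = 72)
  quiet <- function(nm) {
    prof <- platform_profile(nm, noise_sd = 0, background_rate = 0,
                             crossreact_base_fraction = 0,
                             outlier_well_rate = 0,
                             occupancy_dropout = FALSE)
    prof
  }
  profiles <- list(mircury_like = quiet("mircury_like"),
                   taqman_like = quiet("taqman_like"))
  sc <- study_scaffold(panel, off, profiles, n_endogenous = 0L,
                       seed = 73)
  st <- simulate_study(sc, seed = 74)
  rep <- evaluate_study(st, thresholds = c(30, 38))
  # recovery: medians exactly +/-2 with zero spread
  for (nm in names(profiles)) {
    summ <- rep$recovery$per_platform[[nm]]$synthetic$summary
    expect_equal(summ$median, summ$expected)
    expect_equal(summ$variance, c(0, 0))
  }
  # specificity: no cross-reaction, no background, so no false positive
  for (nm in names(profiles)) {
    cur <- rep$specificity[[nm]]$curves$synthetic_1
    expect_true(all(cur$n_false_positive == 0L))
  }
  # linearity: every in-range assay is perfectly linear
  lin <- rep$sensitivity_linearity$per_platform$mircury_like
  expect_equal(lin$linearity_summary$n_assays_r2_ge_cutoff,
               lin$linearity_summary$n_assays)
})
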