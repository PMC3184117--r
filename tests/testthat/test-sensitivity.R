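test_that("replicate correlation is affine invariant and guarded", {
  cfg <- platform_config(38)
  x <- seq(20, 32, length.out = 10)
  ct <- toy_ct(sprintf("a%02d", 1:10), x, x)
  rc <- replicate_correlation(ct, "S1", cfg)
  expect_equal(rc$r, 1)
  expect_equal(rc$n_detected, 10L)

  # constant offset between replicates leaves r at 1
  ct2 <- toy_ct(sprintf("a%02d", 1:10), x, x + 0.7)
  expect_equal(replicate_correlation(ct2, "S1", cfg)$r, 1)

  # fewer than 3 detected assays: undefined, flagged
  ct3 <- toy_ct(c("a1", "a2", "a3"), c(25, NA, NA), c(25, NA, NA))
  rc3 <- replicate_correlation(ct3, "S1", cfg)
  expect_true(rc3$flagged)
  expect_true(is.na(rc3$r))
  expect_equal(rc3$n_detected, 1L)

  # restriction and exclusion lists are honored
  rc4 <- replicate_correlation(ct, "S1", cfg,
                               restrict_assays = sprintf("a%02d", 1:5))
  expect_equal(rc4$n_detected, 5L)
  rc5 <- replicate_correlation(ct, "S1", cfg,
                               exclude_assays = c("a01", "a02"))
  expect_equal(rc5$n_detected, 8L)

  one_rep <- ct_table("S1", "r1", "a1", 25)
  expect_error(replicate_correlation(one_rep, "S1", cfg),
               "exactly two replicates")
})

test_that("simulated duplicates in the study regime correlate >0.97", {
  # ~120 assays spread over ~12 cycles with 0.3 cycles of noise
  panel <- make_panel(60, 60, seed = 31)
  cfg <- platform_config(38)
  params <- simulator_params(noise_sd = 0.3, background_rate = 0,
                             crossreact_base_fraction = 0)
  cat_ <- make_catalog(panel, NULL, "p", seed = 32)
  hom <- build_homology_map(cat_, panel)
  set.seed(33)
  copies <- 10^runif(120, 2.4, 6)  # ~12 cycles of dynamic range
  des <- spike_design(rep("S", 120), panel$mirna_id, copies)
  hits <- 0L
  for (i in 1:20) {
    ct <- simulate_ct_table(des, cat_, hom, params, samples = "S",
                            seed = 100 + i)
    if (replicate_correlation(ct, "S", cfg)$r > 0.97) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("dilution series validates spacing and reads from TSV", {
  pts <- data.frame(point_id = c("d1", "d2", "d3"),
                    copies_per_pcr = c(5000, 500, 50))
  ct <- ct_table(rep(c("d1", "d2", "d3"), each = 4L),
                 rep(c("r1", "r2"), 6L),
                 rep(c("a1", "a1", "a2", "a2"), 3L),
                 rep(c(25, 25.1, 27, 27.2), 3L) +
                   rep(c(0, 3.3, 6.6), each = 4L))
  ser <- dilution_series(ct, pts)
  expect_equal(ser$points$point_id, c("d1", "d2", "d3"))
  bad <- pts
  bad$copies_per_pcr <- c(5000, 700, 50)
  expect_error(dilution_series(ct, bad), "dilution factor")
  expect_no_error(dilution_series(ct, pts[-1, ], 10))
  expect_error(
    dilution_series(ct_table("x", "r1", "a1", 20), pts),
    "no measurements")

  f <- withr::local_tempfile(fileext = ".tsv")
  df <- as.data.frame(ct)
  df$point_id <- df$sample_id
  df$copies_per_pcr <- pts$copies_per_pcr[match(df$point_id,
                                                pts$point_id)]
  write.table(df[, c("point_id", "copies_per_pcr", "replicate_id",
                     "assay_id", "ct")],
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ser2 <- read_dilution_series(f)
  expect_equal(ser2$points$copies_per_pcr, pts$copies_per_pcr)
  expect_equal(sort(unique(ser2$ct$sample_id)), c("d1", "d2", "d3"))
})

test_that("dilution detection is constant without dropout and shrinks with it", {
  panel <- make_panel(20, 20, seed = 41)
  des <- study_design(panel)
  cat_ <- make_catalog(panel, NULL, "p", seed = 42)
  hom <- build_homology_map(cat_, panel)
  cfg <- platform_config(38)
  noiseless <- simulator_params(noise_sd = 0, background_rate = 0,
                                crossreact_base_fraction = 0,
                                occupancy_dropout = FALSE, ct_at_ref = 12)
  ct <- simulate_ct_table(des$design, cat_, hom, noiseless,
                          samples = des$samples$dilution, seed = 1)
  det <- dilution_detection(dilution_series(ct, des$dilution_points),
                            cfg)
  expect_equal(length(unique(det$n_detected)), 1L)

  # Poisson occupancy: counts non-increasing with dilution, 20 seeds
  dropout <- simulator_params(noise_sd = 0, background_rate = 0,
                              crossreact_base_fraction = 0,
                              occupancy_dropout = TRUE, ct_at_ref = 12)
  for (i in 1:20) {
    cti <- simulate_ct_table(des$design, cat_, hom, dropout,
                             samples = des$samples$dilution,
                             seed = 200 + i)
    deti <- dilution_detection(dilution_series(cti, des$dilution_points),
                               cfg)
    expect_true(all(diff(deti$n_detected) <= 0))
    # all_replicates detection never exceeds any_replicate detection
    for (p in deti$point_id) {
      n_any <- sum(detect_calls(cti, p,
                                platform_config(38))$detected)
      expect_lte(deti$n_detected[deti$point_id == p], n_any)
    }
  }
})

test_that("detection comparison matches the enumeration oracle", {
  expect_equal(detection_comparison(5, 5, 10), 1)
  expect_equal(detection_comparison(3, 1, 5),
               oracle_fisher_p(3, 2, 1, 4), tolerance = 1e-12)
  for (n_total in c(4L, 8L, 12L)) {
    for (d1 in seq(0L, n_total, by = 2L)) {
      for (d2 in seq(0L, n_total, by = 2L)) {
        expect_equal(detection_comparison(d1, d2, n_total),
                     oracle_fisher_p(d1, n_total - d1, d2,
                                     n_total - d2),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(detection_comparison(6, 1, 5), "n_total")
})

test_that("assay linearity imputes at threshold and scores r-squared", {
  cfg <- platform_config(38)
  pts <- data.frame(point_id = paste0("d", 1:5),
                    copies_per_pcr = 5000 / 10^(0:4))
  # a perfectly log-linear assay and one that never amplifies
  slope_ct <- 20 + log2(10) * (0:4)
  ct <- ct_table(rep(paste0("d", 1:5), each = 4L),
                 rep(c("r1", "r2"), 10L),
                 rep(c("lin", "lin", "dead", "dead"), 5L),
                 as.numeric(rbind(slope_ct, slope_ct, NA, NA)))
  ser <- dilution_series(ct, pts)
  lin <- assay_linearity(ser, cfg)
  pa <- lin$per_assay
  expect_equal(pa$r_squared[pa$assay_id == "lin"], 1)
  # never-detected assay: all values imputed at threshold, flagged 0
  expect_equal(pa$r_squared[pa$assay_id == "dead"], 0)
  expect_true(pa$flagged[pa$assay_id == "dead"])
  expect_equal(lin$summary$n_assays_r2_ge_cutoff, 1L)
  # by default the weakest point is dropped
  expect_equal(unique(pa$n_points_used), 4L)
  expect_error(assay_linearity(ser, cfg, points_used = 1L),
               "points_used")
})

test_that("low-dropout profiles are more often linear than high-dropout", {
  sc <- small_scaffold()
  cfg_m <- sc$platforms$mircury_like$profile$config
  cfg_t <- sc$platforms$taqman_like$profile$config
  wins <- 0L
  for (i in 1:20) {
    st <- simulate_study(sc, seed = 300 + i)
    com <- spikeval:::common_assays(st)
    lm_ <- assay_linearity(spikeval:::study_dilution_series(st, "mircury_like"),
                           cfg_m, restrict_assays = com$mircury_like)
    lt_ <- assay_linearity(spikeval:::study_dilution_series(st, "taqman_like"),
                           cfg_t, restrict_assays = com$taqman_like)
    f_m <- lm_$summary$n_assays_r2_ge_cutoff / lm_$summary$n_assays
    f_t <- lt_$summary$n_assays_r2_ge_cutoff / lt_$summary$n_assays
    if (f_m > f_t) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})
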