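test_that("detection calls honor the replicate rule and threshold", {
  cfg_any <- platform_config(30, detection_rule = "any_replicate")
  cfg_all <- platform_config(30, detection_rule = "all_replicates")
  ct <- toy_ct(c("a1", "a2", "a3"),
               c(25.0, 25.0, 39.0), c(26.0, NA, 39.5))
  calls_any <- detect_calls(ct, "S1", cfg_any)
  calls_all <- detect_calls(ct, "S1", cfg_all)
  get <- function(calls, a) calls$detected[calls$assay_id == a]
  expect_true(get(calls_any, "a1"))
  expect_true(get(calls_all, "a1"))
  # one undetected replicate fails the all_replicates rule only
  expect_true(get(calls_any, "a2"))
  expect_false(get(calls_all, "a2"))
  # both replicates beyond the threshold fail either rule
  expect_false(get(calls_any, "a3"))
  expect_false(get(calls_all, "a3"))
  # the comparator is inclusive
  ct38 <- toy_ct("a1", 38.0, 38.0)
  cfg38 <- platform_config(38)
  expect_true(detect_calls(ct38, "S1", cfg38)$detected)
  expect_error(detect_calls(ct38, "nope", cfg38), "unknown sample")
})

test_that("fp rate curve counts absent-target detections", {
  # 10 assays targeting absent species, 3 with Ct <= 30
  panel <- mirna_panel("present", "ACGTACGTACGTACGTACGTAC", "A")
  des <- spike_design("S1", "present", 1e6)
  n <- 10L
  cat_ <- assay_catalog(sprintf("a%02d", 1:n), "p",
                        sprintf("absent%02d", 1:n),
                        rep("TTGGCCAATTGGCCAATTGGCC", n))
  cts <- c(25, 27, 29, rep(35, n - 3L))
  ct <- toy_ct(cat_$assay_id, cts, cts)
  hom <- data.frame(assay_id = character(0), platform_id = character(0),
                    mirna_id = character(0), mismatches = integer(0),
                    overhang_left = integer(0),
                    overhang_right = integer(0),
                    aligned_length = integer(0))
  cur <- fp_rate_curve(ct, "S1", des, cat_, c(20, 30, 40), hom)
  expect_equal(cur$n_false_positive, c(0L, 3L, 10L))
  expect_equal(cur$fp_rate, c(0, 0.3, 1))
  expect_equal(cur$n_homology_related, c(0L, 0L, 0L))
  # FP + TN is the constant absent-target assay count
  expect_true(all(cur$n_false_positive + cur$n_true_negative == n))

  # a measured assay missing from the catalog is excluded with warning
  ct2 <- toy_ct(c(cat_$assay_id, "ghost"), c(cts, 20), c(cts, 20))
  expect_warning(
    cur2 <- fp_rate_curve(ct2, "S1", des, cat_, c(20, 30, 40), hom),
    "absent from the catalog")
  expect_equal(cur2$n_false_positive, cur$n_false_positive)
})

test_that("fp rate curves are monotone on simulated studies", {
  st <- small_study(seed = 21)
  for (nm in names(st$platforms)) {
    pl <- st$platforms[[nm]]
    cur <- fp_rate_curve(st$tables[[nm]], "synthetic_1", st$design,
                         pl$catalog, seq(20, 40, 0.5), pl$homology)
    expect_true(all(diff(cur$fp_rate) >= 0))
    expect_true(all(cur$fp_rate >= 0 & cur$fp_rate <= 1))
    expect_true(all(cur$n_homology_related <= cur$n_false_positive))
    expect_equal(length(unique(cur$n_false_positive +
                                 cur$n_true_negative)), 1L)
  }
})

test_that("no-RT threshold suggestion floors the quantile", {
  cfg <- platform_config(38, max_cycles = 40)
  # signals spread over (38.2, 40): a low quantile lands at 38
  no_rt <- toy_ct(sprintf("a%02d", 1:20),
                  seq(38.2, 40.0, length.out = 20),
                  seq(38.3, 39.9, length.out = 20))
  expect_equal(suggest_threshold(no_rt, 0.01, cfg), 38)
  # no numeric signal at all: fall back to the run length
  empty <- toy_ct(c("a1", "a2"), c(NA, NA), c(NA, NA))
  expect_equal(suggest_threshold(empty, 0.01, cfg), 40)
  # single signal: quantile is the value itself, floored
  one <- ct_table("S1", "r1", "a1", 39.7)
  expect_equal(suggest_threshold(one, 0.5, cfg), 39)
  expect_error(suggest_threshold(one, 0, cfg), "quantile")
})

test_that("enrichment tail probabilities match closed forms", {
  # P(X >= 0) is 1 regardless of mode
  expect_equal(enrichment_test(0, 10, 0.2), 1)
  # Poisson lambda = 2, observe 4: 1 - e^-2 (1 + 2 + 2 + 4/3)
  expect_equal(enrichment_test(4, 10, 0.2, mode = "poisson"),
               1 - exp(-2) * (1 + 2 + 2 + 4 / 3), tolerance = 1e-12)
  expect_equal(enrichment_test(4, 10, 0.2, mode = "binomial"),
               oracle_binom_tail(4, 10, 0.2), tolerance = 1e-12)
  expect_warning(p0 <- enrichment_test(0, 0, 0.2), "undefined")
  expect_equal(p0, 1)
  expect_error(enrichment_test(5, 3, 0.2), "n_homology_fp")
  expect_error(enrichment_test(1, 3, 1.2), "expected_fraction")
})

test_that("mismatch-stratified table groups by minimum mismatch", {
  panel <- mirna_panel("present", "ACGTACGTACGTACGTACGTAC", "A")
  des <- spike_design("S1", "present", 1e6)
  # stratum 1: 18 assays, 17 detected; stratum 2: 5 assays, none
  ids1 <- sprintf("one%02d", 1:18)
  ids2 <- sprintf("two%02d", 1:5)
  cat_ <- assay_catalog(c(ids1, ids2), "p",
                        paste0("absent", 1:23),
                        rep("TTGGCCAATTGGCCAATTGGCC", 23))
  hom <- data.frame(
    assay_id = c(ids1, ids1, ids2),  # stratum-1 assays also have a
    platform_id = "p",               # 3-mismatch homolog: min rules
    mirna_id = "present",
    mismatches = c(rep(1L, 18), rep(3L, 18), rep(2L, 5)),
    overhang_left = 0L, overhang_right = 0L, aligned_length = 22L)
  cts <- c(rep(25, 17), 39.5, rep(39.5, 5))
  ct <- toy_ct(c(ids1, ids2), cts, cts)
  tab <- mismatch_stratified_fp(ct, "S1", des, cat_, hom,
                                platform_config(38))
  expect_equal(tab$mismatches, c(1L, 2L))
  expect_equal(tab$n_assays, c(18L, 5L))
  expect_equal(tab$n_false_positive, c(17L, 0L))
  expect_equal(tab$fp_rate_pct, c(94, 0))
})

test_that("cross-reactive simulation yields homology-enriched FPs", {
  st <- small_study(seed = 33)
  pl <- st$platforms$mircury_like
  cur <- fp_rate_curve(st$tables$mircury_like, "synthetic_1", st$design,
                       pl$catalog, c(30, 38), pl$homology)
  at38 <- cur[cur$threshold == 38, ]
  expect_gt(at38$n_false_positive, 0)
  # enrichment over the expected fraction at the platform threshold
  expect_lt(at38$p_enrichment, 0.05)
  expect_gt(at38$n_homology_related / at38$n_false_positive,
            attr(cur, "expected_fraction"))
  # the mismatch table is monotone non-increasing
  tab <- mismatch_stratified_fp(st$tables$mircury_like, "synthetic_1",
                                st$design, pl$catalog, pl$homology,
                                pl$profile$config)
  expect_true(all(diff(tab$fp_rate_pct) <= 0))
})
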