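test_that("control carrier counting is per distinct individual", {
  cfg <- rarity_config()
  q <- cnv("P1", "1", 1e6, 1.1e6)
  empty <- cnv(character(0), character(0), numeric(0), numeric(0))
  expect_equal(control_carrier_count(q, empty, cfg), 0L)
  expect_equal(control_carrier_count(q, cnv("C1", "1", 1e6, 1.1e6), cfg), 1L)
  # one control with TWO overlapping matches still counts once
  two <- rbind(cnv("C1", "1", 1e6, 1.1e6), cnv("C1", "1", 1.00e6, 1.09e6))
  expect_equal(control_carrier_count(q, two, cfg), 1L)
  # same-type requirement: duplication does not match a deletion query
  expect_equal(control_carrier_count(q, cnv("C1", "1", 1e6, 1.1e6,
                                            "duplication"), cfg), 0L)
  cfg_any <- rarity_config(require_same_type = FALSE)
  expect_equal(control_carrier_count(q, cnv("C1", "1", 1e6, 1.1e6,
                                            "duplication"), cfg_any), 1L)
})

test_that("carrier counts match brute force on a constructed panel", {
  cfg <- rarity_config()
  q <- cnv("P1", "2", 0, 100000)
  # 7 controls at RO >= 0.5 (same type), 3 at RO = 0.4, 10 far away
  good <- do.call(rbind, lapply(1:7, function(i) cnv(paste0("G", i), "2", 0, 1e5)))
  near <- do.call(rbind, lapply(1:3, function(i)
    cnv(paste0("N", i), "2", 60000, 160000)))  # ov 40k / len 100k = 0.4
  far <- do.call(rbind, lapply(1:10, function(i)
    cnv(paste0("F", i), "2", 5e6, 5.1e6)))
  panel <- rbind(good, near, far)
  expect_equal(reciprocal_overlap(q, near[1, ]), 0.4)
  expect_equal(control_carrier_count(q, panel, cfg), 7L)
  expect_equal(control_carrier_count(q, panel, cfg), carrier_brute(q, panel, cfg))
  # randomized agreement with brute force
  set.seed(5)
  for (rep in 1:10) {
    rp <- random_intervals(60, chroms = c("1", "2"))
    rp$individual_id <- sample(sprintf("C%02d", 1:20), 60, replace = TRUE)
    rp$cnv_type <- sample(c("deletion", "duplication"), 60, replace = TRUE)
    probe <- random_intervals(1, chroms = "1")
    probe <- cnv("P", probe$chrom, probe$start, probe$end)
    expect_equal(control_carrier_count(probe, rp, cfg),
                 carrier_brute(probe, rp, cfg))
  }
})

test_that("the frequency rule is inclusive at the published panel size", {
  cfg <- rarity_config()
  expect_true(is_rare(0, 10851, cfg))
  expect_true(is_rare(10, 10851, cfg))     # 0.0922% <= 0.1%
  expect_false(is_rare(11, 10851, cfg))    # 0.1014% > 0.1%
  expect_error(is_rare(1, 0, cfg), "positive")
})

test_that("stable-region rule is strict at the 75% boundary", {
  cfg <- rarity_config()
  a <- cnv("P", "1", 0, 100000)
  inside <- genomic_intervals("1", 0, 2e5)
  expect_true(stable_region_pass(a, inside, cfg))
  # exactly 75% covered fails the strict 'more than' comparison
  exact <- genomic_intervals("1", 0, 75000)
  expect_equal(coverage_fraction(a, exact), 0.75)
  expect_false(stable_region_pass(a, exact, cfg))
  two <- genomic_intervals(c("1", "1"), c(0, 60000), c(40000, 100000))
  expect_true(stable_region_pass(a, two, cfg))
})

test_that("the composed filter keeps planted-rare CNVs and audits every exclusion", {
  cfg <- rarity_config()
  stable <- genomic_intervals("1", 0, 1e8)
  # a common CNV carried by 30/100 controls, a rare one carried by none,
  # an undersized one, and one mostly outside stable regions
  common <- cnv("P1", "1", 1e6, 1.2e6)
  rare <- cnv("P1", "1", 5e6, 5.4e6)
  small <- cnv("P2", "1", 7e6, 7e6 + 5000)
  unstable <- cnv("P2", "1", 9.9e7, 9.9e7 + 4e6)  # 25% within stable
  panel <- do.call(rbind, lapply(1:30, function(i)
    cnv(sprintf("C%03d", i), "1", 1e6, 1.2e6)))
  res <- filter_rare_cnvs(rbind(common, rare, small, unstable), panel,
                          stable, cfg, n_controls = 100)
  expect_equal(nrow(res$passed), 1L)
  expect_equal(res$passed$start, 5e6)
  expect_equal(res$audit$fail_reason, c("frequency", "", "size", "unstable_region"))
  expect_equal(res$audit$carrier_count[1], 30L)
  expect_equal(res$audit$stable_fraction[4], 0.25)
  # all-common input: empty output, frequency reasons throughout
  res2 <- filter_rare_cnvs(common, panel, stable, cfg, n_controls = 100)
  expect_equal(nrow(res2$passed), 0L)
  expect_true(all(res2$audit$fail_reason == "frequency"))
})

test_that("whole-chromosome events pass when unmatched (no maximum size rule)", {
  cfg <- rarity_config()
  xlen <- hg19_chrom_lengths()[["X"]]
  whole_x <- cnv("P1", "X", 0, xlen, "duplication")
  stable <- genomic_intervals("X", 0, xlen)
  res <- filter_rare_cnvs(whole_x, cnv("C1", "X", 1e6, 2e6, "duplication"),
                          stable, cfg, n_controls = 100)
  expect_equal(nrow(res$passed), 1L)
})

test_that("filter decisions are monotone in the thresholds", {
  set.seed(21)
  panel <- random_intervals(200, chroms = c("1", "2"))
  panel$individual_id <- sample(sprintf("C%02d", 1:50), 200, replace = TRUE)
  panel$cnv_type <- sample(c("deletion", "duplication"), 200, replace = TRUE)
  probes <- random_intervals(30, chroms = c("1", "2"))
  probes <- cnv(sprintf("P%02d", 1:30), probes$chrom, probes$start,
                pmax(probes$end, probes$start + 10000))
  stable <- genomic_intervals(c("1", "2"), c(0, 0), c(1e6, 1e6))
  loose <- rarity_config(max_control_frequency = 0.5)
  strict <- rarity_config(max_control_frequency = 0.05)
  r_loose <- filter_rare_cnvs(probes, panel, stable, loose, n_controls = 50)
  r_strict <- filter_rare_cnvs(probes, panel, stable, strict, n_controls = 50)
  # raising the frequency cap never removes a passing CNV
  expect_true(all(!r_strict$audit$pass | r_loose$audit$pass))
  # raising the RO threshold never increases a carrier count
  idx <- build_index(panel)
  for (i in seq_len(nrow(probes))) {
    c_low <- control_carrier_count(probes[i, ], idx,
                                   rarity_config(ro_threshold = 0.3))
    c_high <- control_carrier_count(probes[i, ], idx,
                                    rarity_config(ro_threshold = 0.7))
    expect_lte(c_high, c_low)
  }
})
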