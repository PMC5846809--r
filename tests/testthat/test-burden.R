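test_that("BH adjustment reproduces the hand step-up and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # plateau-type outputs (all adjusted values achieved at the top rank)
  # are fixed points of re-adjustment
  expect_equal(bh_adjust(bh_adjust(c(0.01, 0.02, 0.03))),
               bh_adjust(c(0.01, 0.02, 0.03)))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  set.seed(12)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))              # textbook step-up oracle
    expect_true(all(adj >= p - 1e-12))          # never smaller than raw
    expect_true(!is.unsorted(adj[order(p)]))    # monotone in sorted-p order
    expect_true(all(bh_adjust(adj) >= adj - 1e-12))  # re-adjusting never shrinks
  }
})

test_that("chi-square on published stratification tables matches printed statistics", {
  sex <- matrix(c(8, 51, 15, 23), 2, 2, byrow = TRUE)
  gest <- matrix(c(1, 20, 21, 47), 2, 2, byrow = TRUE)
  expect_equal(round(chi_square_contingency(sex)$statistic, 1), 8.6)
  expect_equal(round(chi_square_contingency(gest)$statistic, 1), 5.9)
  expect_equal(chi_square_contingency(sex)$df, 1)
  # perfectly proportional table gives 0
  prop_tab <- matrix(c(10, 20, 5, 10), 2, 2)
  expect_equal(chi_square_contingency(prop_tab)$statistic, 0)
  # Yates correction shrinks the statistic
  expect_lt(chi_square_contingency(sex, yates = TRUE)$statistic,
            chi_square_contingency(sex)$statistic)
})

test_that("chi-square matches the textbook formula on small 2x2 tables", {
  stat_brute <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  for (a in 1:5) for (b in 1:5) for (c in 1:5) for (d in 1:5) {
    tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    expect_equal(chi_square_contingency(tab)$statistic,
                 stat_brute(a, b, c, d), tolerance = 1e-10)
  }
})

test_that("summary t-statistics match published group comparisons", {
  expect_equal(t_from_summary(5, 1, 10, 5, 1, 10)$statistic, 0)
  age <- t_from_summary(8.35, 4.84, 23, 9.67, 4.90, 74)
  expect_equal(round(age$statistic, 1), -1.1)
  expect_equal(age$df, 95)
  quest <- t_from_summary(63.24, 27.1, 23, 63.79, 30.5, 74)
  expect_equal(round(quest$statistic, 1), -0.1)
  # Welch and pooled agree when variances and sizes are equal
  expect_equal(t_from_summary(1, 2, 30, 0, 2, 30, pooled = FALSE)$statistic,
               t_from_summary(1, 2, 30, 0, 2, 30)$statistic)
  # summary-based pooled t equals t.test on the raw data
  set.seed(4)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  tt <- t.test(x, y, var.equal = TRUE)
  ts <- t_from_summary(mean(x), sd(x), 15, mean(y), sd(y), 20)
  expect_equal(ts$statistic, unname(tt$statistic))
  expect_equal(ts$p, tt$p.value)
})

test_that("pLI burden t-test reports direction and group means", {
  set.seed(8)
  ctrl <- rgamma(200, 1, 2)
  same <- pli_burden_test(ctrl, ctrl)
  expect_equal(same$statistic, 0)
  shifted <- pli_burden_test(ctrl + 1, ctrl)
  expect_gt(shifted$statistic, 0)
  expect_equal(shifted$mean_cases - shifted$mean_controls, 1)
})

test_that("carrier burden strata, tests and BH families are wired correctly", {
  exons <- data.frame(chrom = "1", start = c(1000, 5000), end = c(1200, 5200),
                      gene_symbol = c("G1", "G2"),
                      brain_region = c("AMY", "M1C"),
                      timepoint = c("prenatal", "adult"),
                      stringsAsFactors = FALSE)
  cases <- rbind(cnv(sprintf("A%02d", 1:5), "1", 900, 1500))
  ctrls <- rbind(cnv(sprintf("C%02d", 1:10), "1", 900, 1500))
  b <- critical_exon_burden(cases, ctrls, exons, n_cases = 10, n_controls = 20)
  expect_equal(nrow(b), 48L)
  amy <- b[b$brain_region == "AMY" & b$timepoint == "prenatal", ]
  expect_equal(amy$case_carriers, 5L)
  expect_equal(amy$control_carriers, 10L)
  # untouched strata have zero carriers
  expect_equal(sum(b$case_carriers), 5L)
  expect_true(all(b$p_adjusted >= b$p_raw - 1e-12))
  expect_true(all(b$case_carriers <= b$n_cases &
                  b$control_carriers <= b$n_controls))
  # identical carrier proportions: nothing remotely significant one-sided
  expect_gte(amy$p_raw, 0.45)
  expect_true(all(b$p_adjusted > 0.05 | b$case_carriers == 0))
  # a case-only carrier pattern is significant, and the BH family is
  # the 16 regions within the timepoint
  cases2 <- rbind(cnv(sprintf("A%02d", 1:9), "1", 900, 1500))
  b2 <- critical_exon_burden(cases2, ctrls[0, ], exons, 10, 20)
  amy2 <- b2[b2$brain_region == "AMY" & b2$timepoint == "prenatal", ]
  expect_lt(amy2$p_raw, 0.05)
  expect_equal(amy2$p_adjusted, min(amy2$p_raw * 16, 1))
  expect_error(critical_exon_burden(cases, ctrls, exons, 0, 20), "positive")
  # prebuilt index gives identical results
  ce <- index_critical_exons(exons)
  expect_equal(critical_exon_burden(cases, ctrls, ce, 10, 20), b)
})

test_that("score-test variant is one-sided for case enrichment", {
  exons <- data.frame(chrom = "1", start = 1000, end = 1200,
                      gene_symbol = "G1", brain_region = "AMY",
                      timepoint = "prenatal", stringsAsFactors = FALSE)
  cases <- cnv(sprintf("A%02d", 1:8), "1", 900, 1500)
  ctrls <- cnv(sprintf("C%02d", 1:2), "1", 900, 1500)
  b <- critical_exon_burden(cases, ctrls, exons, 10, 20, test = "score")
  amy <- b[b$brain_region == "AMY" & b$timepoint == "prenatal", ]
  expect_lt(amy$p_raw, 0.05)
  depleted <- critical_exon_burden(ctrls, cases, exons, 20, 10, test = "score")
  expect_gt(depleted$p_raw[depleted$brain_region == "AMY" &
                           depleted$timepoint == "prenatal"], 0.5)
})

test_that("cohort stratification reproduces the published tests and guards input", {
  # rebuild the published sex and gestation contingency tables from rows
  cov <- data.frame(
    individual_id = sprintf("I%03d", 1:97),
    sex = c(rep("male", 8), rep("female", 15),       # CNV group
            rep("male", 51), rep("female", 23)),     # non-CNV group
    stringsAsFactors = FALSE)
  gest <- c(rep("preterm", 1), rep("term", 21), NA,  # CNV: 1/21, 1 missing
            rep("preterm", 20), rep("term", 47), rep(NA, 7))
  cov$gestation <- gest
  cnv_ids <- cov$individual_id[1:23]
  res <- stratify_cohort(cov, cnv_ids)
  expect_equal(round(res$statistic[res$variable == "sex"], 1), 8.6)
  expect_equal(round(res$statistic[res$variable == "gestation"], 1), 5.9)
  # missing gestation rows are excluded listwise for that variable only
  expect_equal(res$n_cnv[res$variable == "gestation"], 22)
  expect_equal(res$n_cnv[res$variable == "sex"], 23)
  expect_error(stratify_cohort(cov, cov$individual_id), "degenerate")
  expect_error(stratify_cohort(cov, character(0)), "degenerate")
})

test_that("independent covariates are rarely significant under stratification", {
  set.seed(31)
  hits <- 0
  for (rep in 1:40) {
    cov <- data.frame(individual_id = sprintf("I%02d", 1:60),
                      score = rnorm(60), stringsAsFactors = FALSE)
    res <- stratify_cohort(cov, sample(cov$individual_id, 15))
    hits <- hits + (res$p < 0.05)
  }
  expect_lte(hits, 8)  # ~2 expected at the 5% level over 40 replicates
})
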