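#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `adj_(i) = min_{j >= i} ( p_(j) * m / j )` clipped at 1,
#' order-preserving in the input. Thin, named wrapper over
#' `stats::p.adjust(method = "BH")` so the multiple-testing policy of
#' the burden module is a single documented surface.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

## one-sided (enrichment in group 1) hypergeometric mid-p for a 2x2
## carrier table; near-nominal type-I error where the exact test is
## conservative. Conditions on the carrier margin.
midp_greater <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  phyper(x1 - 1, n1, n2, k, lower.tail = FALSE) - 0.5 * dhyper(x1, n1, n2, k)
}

#' Index a critical-exon label track for carrier queries
#'
#' Deduplicates exon intervals, assigns each (brain_region,
#' timepoint) label an integer stratum, and builds the overlap
#' index. Build once and pass to [critical_exon_burden()] when
#' running many cohorts against the same track.
#'
#' @param critical_exons long-format track: chrom, start, end,
#'   brain_region, timepoint (one row per label).
#' @return object of class `ce_index`.
#' @export
index_critical_exons <- function(critical_exons) {
  strata <- expand.grid(brain_region = brain_regions(),
                        timepoint = timepoints(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sid <- match(paste(critical_exons$brain_region, critical_exons$timepoint),
               paste(strata$brain_region, strata$timepoint))
  if (any(is.na(sid))) {
    stop("critical exon track has labels outside the region/timepoint vocabulary",
         call. = FALSE)
  }
  key <- paste(critical_exons$chrom, critical_exons$start, critical_exons$end)
  first <- !duplicated(key)
  ux <- critical_exons[first, c("chrom", "start", "end"), drop = FALSE]
  exon_id <- match(key, key[first])
  lab <- unique(data.frame(exon_id = exon_id, stratum = sid))
  by_exon <- split(lab$stratum, factor(lab$exon_id, levels = seq_len(nrow(ux))))
  structure(list(gr = if (nrow(ux)) gi_to_granges(ux) else NULL,
                 by_exon = by_exon, n_strata = nrow(strata),
                 strata = strata),
            class = "ce_index")
}

## distinct carriers per stratum: integer counts of individuals with
## >= 1 CNV hitting >= 1 exon of the stratum
stratum_carriers <- function(cnvs, ce) {
  if (nrow(cnvs) == 0L || is.null(ce$gr)) return(integer(ce$n_strata))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gi_to_granges(cnvs), ce$gr))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (!length(q)) return(integer(ce$n_strata))
  ind <- as.integer(factor(cnvs$individual_id))[q]
  strat <- ce$by_exon[s]
  len <- lengths(strat)
  key <- unique((rep(ind, len) - 1) * ce$n_strata + unlist(strat, use.names = FALSE))
  tabulate(((key - 1) %% ce$n_strata) + 1L, nbins = ce$n_strata)
}

#' Critical-exon carrier burden by brain region and timepoint
#'
#' For each of the 16 brain regions x 3 developmental timepoints, an
#' individual is a *carrier* when at least one of their (post
#' rarity-filter) CNVs intersects at least one critical exon labeled
#' with that region and timepoint. Case and control carrier
#' proportions are compared with a one-sided test for enrichment in
#' cases; p-values are Benjamini-Hochberg adjusted across the 16
#' regions within each timepoint (the per-timepoint family; set
#' `bh_scope = "global"` for a single 48-test family).
#'
#' The default test is the hypergeometric mid-p (one-sided), which
#' holds close-to-nominal type-I error at these carrier rates where
#' the plain exact test is conservative; `test = "score"` gives the
#' one-sided two-proportion score (z) test. The reported `statistic`
#' is the sample odds ratio of the 2x2 carrier table.
#'
#' @param case_cnvs,control_cnvs CNV data.frames with `individual_id`.
#' @param critical_exons long-format track (chrom, start, end,
#'   brain_region, timepoint; one row per label), or a prebuilt
#'   [index_critical_exons()] object.
#' @param n_cases,n_controls group sizes (must be positive; carriers
#'   are counted among these).
#' @param test `"midp"` (default) or `"score"`.
#' @param bh_scope `"timepoint"` (default) or `"global"`.
#' @return data.frame of 48 rows: brain_region, timepoint,
#'   case_carriers, control_carriers, n_cases, n_controls, statistic,
#'   p_raw, p_adjusted.
#' @export
critical_exon_burden <- function(case_cnvs, control_cnvs, critical_exons,
                                 n_cases, n_controls,
                                 test = c("midp", "score"),
                                 bh_scope = c("timepoint", "global")) {
  test <- match.arg(test)
  bh_scope <- match.arg(bh_scope)
  if (n_cases <= 0 || n_controls <= 0) {
    stop("group sizes must be positive", call. = FALSE)
  }
  ce <- if (inherits(critical_exons, "ce_index")) critical_exons else
    index_critical_exons(critical_exons)
  strata <- ce$strata
  ca <- stratum_carriers(case_cnvs, ce)
  co <- stratum_carriers(control_cnvs, ce)
  if (any(ca > n_cases) || any(co > n_controls)) {
    stop("carrier count exceeds group size; check individual ids",
         call. = FALSE)
  }
  out <- strata
  out$case_carriers <- as.integer(ca)
  out$control_carriers <- as.integer(co)
  out$n_cases <- n_cases
  out$n_controls <- n_controls
  x1 <- out$case_carriers; x2 <- out$control_carriers
  or_num <- x1 * (n_controls - x2)
  or_den <- x2 * (n_cases - x1)
  out$statistic <- ifelse(or_den == 0, Inf, or_num / or_den)
  out$statistic[or_num == 0 & or_den == 0] <- NA_real_
  if (test == "midp") {
    out$p_raw <- pmin(1, pmax(0, midp_greater(x1, n_cases, x2, n_controls)))
  } else {
    phat <- (x1 + x2) / (n_cases + n_controls)
    se <- sqrt(phat * (1 - phat) * (1 / n_cases + 1 / n_controls))
    z <- ifelse(se == 0, 0, (x1 / n_cases - x2 / n_controls) / se)
    out$p_raw <- pnorm(z, lower.tail = FALSE)
  }
  if (bh_scope == "timepoint") {
    out$p_adjusted <- stats::ave(out$p_raw, out$timepoint, FUN = bh_adjust)
  } else {
    out$p_adjusted <- bh_adjust(out$p_raw)
  }
  out
}

#' pLI deletion-burden t-test
#'
#' Unpaired two-sample t-test comparing per-individual pLI sums
#' (genes impacted by deletions, each gene once) between cases and
#' controls. Pooled-variance by default; `pooled = FALSE` gives the
#' Welch test.
#'
#' @param case_sums,control_sums numeric vectors of per-individual
#'   pLI sums (zeros included for individuals without deletions).
#' @param pooled use the pooled-variance t (default TRUE).
#' @return data.frame: variable, test, mean_cases, mean_controls,
#'   statistic, df, p.
#' @export
pli_burden_test <- function(case_sums, control_sums, pooled = TRUE) {
  tt <- t.test(case_sums, control_sums, var.equal = pooled)
  data.frame(variable = "pli_sum", test = "t_test",
             mean_cases = mean(case_sums),
             mean_controls = mean(control_sums),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction by default (`yates = FALSE`), matching
#' standard reporting of cohort stratification tables; df =
#' (r-1)(c-1).
#'
#' @param tab r x c matrix of counts.
#' @param yates apply the Yates continuity correction (2x2 only).
#' @param variable label for the report.
#' @return data.frame: variable, test, statistic, df, p.
#' @export
chi_square_contingency <- function(tab, yates = FALSE, variable = "table") {
  tab <- as.matrix(tab)
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  data.frame(variable = variable, test = "chi_square",
             statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value, stringsAsFactors = FALSE)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t from group means, SDs and sizes
#' (Welch-Satterthwaite with `pooled = FALSE`), for re-analysis of
#' published group summaries.
#'
#' @param mean1,sd1,n1 group 1 summary.
#' @param mean2,sd2,n2 group 2 summary.
#' @param pooled pooled-variance (default TRUE) or Welch.
#' @param variable label for the report.
#' @return data.frame: variable, test, statistic, df, p.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE,
                           variable = "summary") {
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- (mean1 - mean2) / se
  data.frame(variable = variable, test = "t_test", statistic = stat,
             df = df, p = 2 * pt(-abs(stat), df), stringsAsFactors = FALSE)
}

#' Stratify a cohort by CNV status and test covariates
#'
#' Splits individuals into CNV-positive (ids in `cnv_positive_ids`)
#' and CNV-negative groups and, per configured variable, runs a
#' chi-square test on the contingency table (categorical) or an
#' unpaired t-test (continuous). Rows with a missing value are
#' excluded listwise per variable. Errors if either group is empty
#' ("degenerate stratification").
#'
#' @param covariates data.frame with `individual_id` and covariate
#'   columns (from [read_covariates()]).
#' @param cnv_positive_ids ids of the CNV-positive group.
#' @param variables named character vector mapping covariate column
#'   to test: `"chi_square"` or `"t_test"`; default: factors/
#'   characters get chi-square, numerics get the t-test.
#' @param yates continuity correction for the chi-square tests.
#' @return data.frame of one test per variable: variable, test,
#'   n_cnv, n_non_cnv, statistic, df, p.
#' @export
stratify_cohort <- function(covariates, cnv_positive_ids, variables = NULL,
                            yates = FALSE) {
  grp <- covariates$individual_id %in% cnv_positive_ids
  if (all(grp) || !any(grp)) {
    stop("degenerate stratification: one group is empty", call. = FALSE)
  }
  cols <- setdiff(names(covariates), "individual_id")
  if (is.null(variables)) {
    variables <- vapply(covariates[cols], function(v)
      if (is.numeric(v)) "t_test" else "chi_square", character(1))
  }
  out <- lapply(names(variables), function(v) {
    x <- covariates[[v]]
    keep <- !is.na(x)
    xg <- x[keep]; gg <- grp[keep]
    if (variables[[v]] == "chi_square") {
      tab <- table(factor(gg, levels = c(TRUE, FALSE)), xg)
      res <- chi_square_contingency(tab, yates = yates, variable = v)
    } else {
      tt <- t.test(xg[gg], xg[!gg], var.equal = TRUE)
      res <- data.frame(variable = v, test = "t_test",
                        statistic = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value,
                        stringsAsFactors = FALSE)
    }
    res$n_cnv <- sum(gg); res$n_non_cnv <- sum(!gg)
    res[, c("variable", "test", "n_cnv", "n_non_cnv", "statistic", "df", "p")]
  })
  do.call(rbind, out)
}
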