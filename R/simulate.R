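#' Synthetic cohort configuration
#'
#' Parameters of the synthetic trio cohort and control panel. The
#' defaults emulate the study conditions of a 97-trio hemiplegic
#' cerebral palsy cohort screened against 10,851 population controls:
#' about 3.5 stringent CNVs per proband (340/97), sizes log-uniform
#' from 10 kb to 5 Mb plus rare whole-chromosome events, a 65:35
#' deletion:duplication mix, planted de novo events in 7% of
#' probands, common CNV polymorphisms the rarity filter must remove,
#' 90% of the genome copy-number stable, and gene models carrying
#' pLI scores and critical-exon labels over 16 brain regions x 3
#' developmental timepoints.
#'
#' @param n_trios number of proband-mother-father trios.
#' @param n_controls population control panel size.
#' @param n_matched_controls platform-matched control subset used for
#'   burden replicates.
#' @param cnv_rate mean background CNVs per individual (Poisson).
#' @param size_min_bp,size_max_bp log-uniform CNV size range.
#' @param del_fraction probability a CNV is a deletion.
#' @param de_novo_rate per-proband probability of a planted de novo
#'   event.
#' @param aneuploidy_prob per-proband probability of a planted
#'   whole-chromosome de novo event.
#' @param n_common_loci,common_freq_range common CNV polymorphism
#'   loci and their population frequency range.
#' @param common_carrier_prob per-locus probability that a proband
#'   carries the common CNV (set above the population frequency so
#'   the filter stage is exercised in small cohorts).
#' @param stable_fraction fraction of each chromosome that is
#'   copy-number stable.
#' @param n_genes,mean_exons,exon_len_bp gene model shape.
#' @param pli_high_frac,pli_low_frac pLI mixture: point-mass-like
#'   components near 1 and near 0 (remainder uniform).
#' @param critical_exon_prob probability a coding exon is critical.
#' @param region_label_prob per-region labeling probability of a
#'   critical exon.
#' @param timepoint_probs per-gene developmental window probabilities
#'   (prenatal, child_adolescent, adult).
#' @param n_disease_genes size of the synthetic disease-gene list.
#' @param burden_effect per-case probability of one planted CNV
#'   targeting a prenatal critical exon (burden enrichment).
#' @param jitter_mode `"safe"` keeps transmitted child-parent
#'   reciprocal overlap >= 0.9; `"adversarial"` jitters near the 0.5
#'   match threshold for boundary testing.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 97, n_controls = 10851,
                       n_matched_controls = 2000,
                       cnv_rate = 3.5,
                       size_min_bp = 1e4, size_max_bp = 5e6,
                       del_fraction = 0.65,
                       de_novo_rate = 0.07,
                       aneuploidy_prob = 0.005,
                       n_common_loci = 12,
                       common_freq_range = c(0.01, 0.05),
                       common_carrier_prob = 0.15,
                       stable_fraction = 0.9,
                       n_genes = 500, mean_exons = 8, exon_len_bp = 150,
                       pli_high_frac = 0.17, pli_low_frac = 0.53,
                       critical_exon_prob = 0.3,
                       region_label_prob = 0.6,
                       timepoint_probs = c(prenatal = 0.4,
                                           child_adolescent = 0.3,
                                           adult = 0.3),
                       n_disease_genes = 30,
                       burden_effect = 0.25,
                       jitter_mode = c("safe", "adversarial")) {
  jitter_mode <- match.arg(jitter_mode)
  probs <- c(del_fraction, de_novo_rate, aneuploidy_prob,
             common_carrier_prob, stable_fraction, critical_exon_prob,
             region_label_prob, burden_effect, common_freq_range)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (size_min_bp <= 0 || size_max_bp <= size_min_bp) {
    stop("need 0 < size_min_bp < size_max_bp", call. = FALSE)
  }
  if (abs(sum(timepoint_probs) - 1) > 1e-8) {
    stop("timepoint_probs must sum to 1", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

## -- internal samplers -------------------------------------------------

## n random CNVs anywhere on the genome (chromosome prob ~ length)
random_cnvs <- function(n, cfg, chrom_lengths = hg19_chrom_lengths()) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cnv_type = character(0),
                      stringsAsFactors = FALSE))
  }
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  size <- round(exp(runif(n, log(cfg$size_min_bp), log(cfg$size_max_bp))))
  size <- pmin(size, chrom_lengths[chrom] - 1)
  start <- floor(runif(n) * (chrom_lengths[chrom] - size))
  data.frame(chrom = chrom, start = start, end = start + size,
             cnv_type = ifelse(runif(n) < cfg$del_fraction,
                               "deletion", "duplication"),
             stringsAsFactors = FALSE, row.names = NULL)
}

## n random CNVs fully inside copy-number-stable regions
stable_cnvs <- function(n, cfg, stable_regions) {
  if (n == 0L) return(random_cnvs(0L, cfg))
  w <- stable_regions$end - stable_regions$start
  idx <- sample.int(nrow(stable_regions), n, replace = TRUE, prob = w)
  size <- round(exp(runif(n, log(cfg$size_min_bp), log(cfg$size_max_bp))))
  size <- pmin(size, w[idx] - 1)
  start <- stable_regions$start[idx] +
    floor(runif(n) * (w[idx] - size))
  data.frame(chrom = stable_regions$chrom[idx], start = start,
             end = start + size,
             cnv_type = ifelse(runif(n) < cfg$del_fraction,
                               "deletion", "duplication"),
             stringsAsFactors = FALSE, row.names = NULL)
}

## boundary jitter for transmitted copies; "safe" keeps RO >= 0.9
jitter_cnv <- function(cnv, mode) {
  len <- cnv$end - cnv$start
  j <- if (mode == "safe") 0.025 else 0.24
  d1 <- round(runif(nrow(cnv), -j, j) * len)
  d2 <- round(runif(nrow(cnv), -j, j) * len)
  out <- cnv
  out$start <- pmax(0, cnv$start + d1)
  out$end <- pmax(out$start + 1, cnv$end + d2)
  out
}

#' The "hg19-mini" annotation fixture
#'
#' A small deterministic gene and locus fixture on approximate
#' GRCh37/hg19 coordinates, covering the genes and genomic-disorder
#' loci recurrently seen in hemiplegic-CP CNV findings: LAMA1, PTPRM
#' and LRRC30 in 18p11.23-18p11.31; DMD and FTHL17 in Xp21.2; GRIK2
#' (6q16.3); DIP2C (10p15.3); CNTNAP2 (7q35); STS (Xp22.31); PMP22
#' (17p12); and the 22q11.21, 17p12 and Xp22.31 disorder loci. Gene
#' spans are hg19-approximate; exon layouts and pLI values are
#' synthetic stand-ins (uniform exon tiling of each span), adequate
#' for exercising coding-exon impact logic but not for clinical
#' interpretation.
#'
#' @return list: `genes`, `exons` (as [read_gene_models()]),
#'   `syndrome_loci`, `pli`, `disease_genes`.
#' @export
hg19_mini_annotations <- function() {
  genes <- data.frame(
    gene_symbol = c("LAMA1", "LRRC30", "PTPRM", "DMD", "FTHL17", "GRIK2",
                    "DIP2C", "CNTNAP2", "STS", "PMP22"),
    chrom = c("18", "18", "18", "X", "X", "6", "10", "7", "X", "17"),
    start = c(6941743, 7231559, 7566782, 31137345, 32930000, 101841584,
              320130, 145813453, 7137497, 15133096),
    end = c(7117813, 7232605, 8407008, 33229673, 32931400, 102517958,
            735608, 148118090, 7272851, 15168643),
    stringsAsFactors = FALSE)
  exon_tile <- function(g, n) {
    span <- genes$end[g] - genes$start[g]
    at <- round(seq(0, span - 200, length.out = n))
    data.frame(gene_symbol = genes$gene_symbol[g], chrom = genes$chrom[g],
               start = genes$start[g] + at, end = genes$start[g] + at + 180,
               exon_rank = seq_len(n), coding = TRUE,
               stringsAsFactors = FALSE)
  }
  n_ex <- c(10, 1, 12, 20, 1, 8, 10, 24, 6, 4)
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)),
                                 function(g) exon_tile(g, n_ex[g])))
  loci <- data.frame(
    locus = c("22q11.21", "17p12", "Xp22.31"),
    syndrome = c("22q11.2 duplication/deletion syndrome",
                 "hereditary neuropathy with liability to pressure palsies",
                 "steroid sulfatase deficiency"),
    chrom = c("22", "17", "X"),
    start = c(18894835, 14097915, 6455812),
    end = c(21505417, 15470903, 8133195),
    stringsAsFactors = FALSE)
  pli <- data.frame(
    gene_symbol = genes$gene_symbol,
    pli = c(1.00, 0.01, 0.98, 0.11, 0.02, 0.98, 0.99, 0.79, 0.05, 0.23),
    stringsAsFactors = FALSE)
  disease <- data.frame(
    gene_symbol = c("DMD", "GRIK2", "DIP2C", "CNTNAP2", "CNTN4", "CNTN6",
                    "PMP22", "LAMA1", "PTPRM", "SCN3B", "EPHA6", "KCNK9",
                    "ASTN2", "MCPH1", "USP7", "ABAT", "DLGAP1", "SEMA5A",
                    "DPP6", "MYO15A"),
    category = "neurodevelopmental_or_muscular",
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, syndrome_loci = loci, pli = pli,
       disease_genes = disease)
}

#' Generate the synthetic annotation bundle
#'
#' Builds mutually consistent reference tracks for a synthetic
#' genome on real hg19 chromosome lengths: copy-number-stable
#' regions covering `stable_fraction` of each chromosome (5 Mb
#' tiling with random unstable holes), random gene models with
#' non-overlapping exons, per-gene pLI from a near-0 / near-1 /
#' uniform mixture, critical-exon labels (per-gene developmental
#' timepoint, per-exon Bernoulli region labels over the 16 regions),
#' a disease-gene list, common CNV polymorphism loci with population
#' frequencies, and the deterministic [hg19_mini_annotations()]
#' genes and disorder loci merged in.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (identical cfg+seed give identical
#'   output).
#' @return list: gene_models (genes, exons), stable_regions,
#'   syndrome_loci, pli, critical_exons, disease_genes, common_loci,
#'   chrom_lengths.
#' @export
generate_annotations <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  cl <- hg19_chrom_lengths()
  ## stable regions: 5 Mb tiles, drop ~ (1 - stable_fraction) of them
  stable <- do.call(rbind, lapply(names(cl), function(ch) {
    edges <- unique(c(seq(0, cl[[ch]], by = 5e6), cl[[ch]]))
    n_tile <- length(edges) - 1
    drop <- sample.int(n_tile, round((1 - cfg$stable_fraction) * n_tile))
    keep <- setdiff(seq_len(n_tile), drop)
    if (!length(keep)) return(NULL)
    r <- IRanges::reduce(IRanges::IRanges(edges[keep] + 1, edges[keep + 1]))
    data.frame(chrom = ch, start = IRanges::start(r) - 1,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  rownames(stable) <- NULL
  ## random gene models
  fix <- hg19_mini_annotations()
  n <- cfg$n_genes
  n_ex <- 1L + rpois(n, cfg$mean_exons - 1)
  sym <- sprintf("SYNG%04d", seq_len(n))
  exons <- lapply(seq_len(n), function(i) {
    gaps <- round(runif(n_ex[i], 500, 8000))
    st <- cumsum(c(0, head(gaps, -1) + cfg$exon_len_bp))
    data.frame(gene_symbol = sym[i], start_off = st,
               exon_rank = seq_len(n_ex[i]), stringsAsFactors = FALSE)
  })
  span <- vapply(exons, function(e) max(e$start_off) + cfg$exon_len_bp,
                 numeric(1))
  chrom <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
  gstart <- floor(runif(n) * (cl[chrom] - span))
  genes <- data.frame(gene_symbol = sym, chrom = chrom, start = gstart,
                      end = gstart + span, stringsAsFactors = FALSE,
                      row.names = NULL)
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- exons[[i]]
    data.frame(gene_symbol = e$gene_symbol, chrom = chrom[i],
               start = gstart[i] + e$start_off,
               end = gstart[i] + e$start_off + cfg$exon_len_bp,
               exon_rank = e$exon_rank, coding = TRUE,
               stringsAsFactors = FALSE)
  }))
  genes <- rbind(genes, fix$genes)
  exons <- rbind(exons, fix$exons[, names(exons)])
  rownames(genes) <- rownames(exons) <- NULL
  ## pLI mixture
  u <- runif(nrow(genes))
  pli <- ifelse(u < cfg$pli_high_frac, rbeta(nrow(genes), 40, 1),
         ifelse(u < cfg$pli_high_frac + cfg$pli_low_frac,
                rbeta(nrow(genes), 1, 40), runif(nrow(genes))))
  pli_tab <- data.frame(gene_symbol = genes$gene_symbol, pli = pli,
                        stringsAsFactors = FALSE)
  pli_tab$pli[match(fix$pli$gene_symbol, pli_tab$gene_symbol)] <- fix$pli$pli
  ## critical exons: per-gene timepoint, per-exon region labels
  tp_gene <- sample(timepoints(), nrow(genes), replace = TRUE,
                    prob = cfg$timepoint_probs)
  names(tp_gene) <- genes$gene_symbol
  is_crit <- runif(nrow(exons)) < cfg$critical_exon_prob
  crit <- exons[is_crit, , drop = FALSE]
  labels <- lapply(seq_len(nrow(crit)), function(i) {
    regs <- brain_regions()[runif(16) < cfg$region_label_prob]
    if (!length(regs)) regs <- sample(brain_regions(), 1)
    data.frame(chrom = crit$chrom[i], start = crit$start[i],
               end = crit$end[i], gene_symbol = crit$gene_symbol[i],
               brain_region = regs,
               timepoint = tp_gene[[crit$gene_symbol[i]]],
               stringsAsFactors = FALSE)
  })
  critical_exons <- do.call(rbind, labels)
  rownames(critical_exons) <- NULL
  ## disease genes: synthetic picks plus the fixture list
  dg <- data.frame(gene_symbol = sample(sym, cfg$n_disease_genes),
                   category = "synthetic_disease_gene",
                   stringsAsFactors = FALSE)
  ## common CNV polymorphism loci
  common <- random_cnvs(cfg$n_common_loci, cfg, cl)
  csize <- round(exp(runif(cfg$n_common_loci, log(5e4), log(5e5))))
  common$end <- pmin(common$start + csize, cl[common$chrom])
  common$locus_id <- sprintf("COMMON%02d", seq_len(cfg$n_common_loci))
  common$frequency <- runif(cfg$n_common_loci, cfg$common_freq_range[1],
                            cfg$common_freq_range[2])
  rownames(common) <- NULL
  list(gene_models = list(genes = genes, exons = exons),
       stable_regions = stable,
       syndrome_loci = fix$syndrome_loci,
       pli = pli_tab,
       critical_exons = critical_exons,
       disease_genes = rbind(dg, fix$disease_genes),
       common_loci = common,
       chrom_lengths = cl)
}

#' Generate a fully labeled synthetic trio cohort and control panel
#'
#' Produces CNV call tables for probands, parents and population
#' controls, the PED pedigree, and a truth table labeling every
#' proband CNV:
#'
#' * `transmitted_maternal` / `transmitted_paternal` — background
#'   rare CNVs placed inside copy-number-stable regions and copied
#'   into the transmitting parent with boundary jitter (reciprocal
#'   overlap kept >= 0.9 in `"safe"` mode);
#' * `de_novo_planted` — present only in the proband (including rare
#'   whole-chromosome events);
#' * `common` — CNVs at the common polymorphism loci, carried by
#'   controls at the configured population frequency (binomial
#'   sampling) and by a transmitting parent.
#'
#' Parents and controls additionally carry their own background CNVs
#' at the same Poisson rate. Identical cfg + seed reproduce the
#' output exactly.
#'
#' @param cfg a [sim_config()].
#' @param annotations bundle from [generate_annotations()].
#' @param seed integer seed.
#' @return list: probands, parents, controls (CNV data.frames),
#'   pedigree, truth, n_controls.
#' @export
generate_cohort <- function(cfg = sim_config(),
                            annotations = generate_annotations(cfg),
                            seed = 1) {
  set.seed(seed + 1L)
  cl <- annotations$chrom_lengths
  nt <- cfg$n_trios
  pid <- sprintf("P%03d", seq_len(nt))
  mid <- sprintf("M%03d", seq_len(nt))
  fid <- sprintf("F%03d", seq_len(nt))
  ped <- data.frame(family_id = sprintf("FAM%03d", seq_len(nt)),
                    individual_id = c(pid, mid, fid),
                    father_id = c(fid, rep("0", 2 * nt)),
                    mother_id = c(mid, rep("0", 2 * nt)),
                    sex = c(sample(c("male", "female"), nt, replace = TRUE,
                                   prob = c(0.6, 0.4)),
                            rep("female", nt), rep("male", nt)),
                    phenotype = c(rep("2", nt), rep("1", 2 * nt)),
                    stringsAsFactors = FALSE)
  ped$role <- c(rep("proband", nt), rep("parent", 2 * nt))
  ped$incomplete_trio <- FALSE

  truth <- list(); proband <- list(); parent_extra <- list()
  for (i in seq_len(nt)) {
    ## transmitted background rare CNVs, inside stable regions
    n_bg <- rpois(1, cfg$cnv_rate)
    rows <- stable_cnvs(n_bg, cfg, annotations$stable_regions)
    from_mother <- runif(n_bg) < 0.5
    rows$truth <- ifelse(from_mother, "transmitted_maternal",
                         "transmitted_paternal")
    rows$parent_id <- ifelse(from_mother, mid[i], fid[i])
    ## planted de novo
    if (runif(1) < cfg$de_novo_rate) {
      dn <- stable_cnvs(1L, cfg, annotations$stable_regions)
      dn$truth <- "de_novo_planted"; dn$parent_id <- NA_character_
      rows <- rbind(rows, dn)
    }
    ## planted whole-chromosome de novo event
    if (runif(1) < cfg$aneuploidy_prob) {
      ch <- sample(names(cl), 1)
      an <- data.frame(chrom = ch, start = 0, end = cl[[ch]],
                       cnv_type = sample(c("deletion", "duplication"), 1),
                       truth = "de_novo_planted", parent_id = NA_character_,
                       stringsAsFactors = FALSE)
      rows <- rbind(rows, an)
    }
    ## planted common CNVs (carried by a transmitting parent too)
    carry <- which(runif(nrow(annotations$common_loci)) < cfg$common_carrier_prob)
    if (length(carry)) {
      cm <- annotations$common_loci[carry,
              c("chrom", "start", "end", "cnv_type"), drop = FALSE]
      cm <- jitter_cnv(cm, "safe")
      cm$truth <- "common"
      cm$parent_id <- ifelse(runif(length(carry)) < 0.5, mid[i], fid[i])
      rows <- rbind(rows, cm)
    }
    if (nrow(rows)) {
      rows$individual_id <- pid[i]
      proband[[i]] <- rows[, c("individual_id", "chrom", "start", "end",
                               "cnv_type")]
      truth[[i]] <- rows[, c("individual_id", "chrom", "start", "end",
                             "cnv_type", "truth", "parent_id")]
      tr <- rows[!is.na(rows$parent_id), , drop = FALSE]
      if (nrow(tr)) {
        tcopy <- jitter_cnv(tr[, c("chrom", "start", "end", "cnv_type")],
                            cfg$jitter_mode)
        tcopy$individual_id <- tr$parent_id
        parent_extra[[i]] <- tcopy[, c("individual_id", "chrom", "start",
                                       "end", "cnv_type")]
      }
    }
  }
  proband <- do.call(rbind, proband)
  truth <- do.call(rbind, truth)
  rownames(proband) <- rownames(truth) <- NULL

  ## parents: own background CNVs plus transmitted copies
  par_ids <- c(mid, fid)
  n_own <- rpois(2 * nt, cfg$cnv_rate)
  own <- random_cnvs(sum(n_own), cfg, cl)
  own$individual_id <- rep(par_ids, n_own)
  parents <- rbind(own[, c("individual_id", "chrom", "start", "end",
                           "cnv_type")],
                   do.call(rbind, parent_extra))
  rownames(parents) <- NULL

  ## control panel: background CNVs + common loci at population frequency
  cid <- sprintf("C%05d", seq_len(cfg$n_controls))
  n_c <- rpois(cfg$n_controls, cfg$cnv_rate)
  ctrl <- random_cnvs(sum(n_c), cfg, cl)
  ctrl$individual_id <- rep(cid, n_c)
  common_rows <- lapply(seq_len(nrow(annotations$common_loci)), function(j) {
    lo <- annotations$common_loci[j, ]
    carriers <- which(runif(cfg$n_controls) < lo$frequency)
    if (!length(carriers)) return(NULL)
    cc <- jitter_cnv(lo[rep(1, length(carriers)),
                        c("chrom", "start", "end", "cnv_type")], "safe")
    cc$individual_id <- cid[carriers]
    cc
  })
  controls <- rbind(ctrl[, c("individual_id", "chrom", "start", "end",
                             "cnv_type")],
                    do.call(rbind, common_rows)[, c("individual_id", "chrom",
                                                    "start", "end",
                                                    "cnv_type")])
  rownames(controls) <- NULL

  list(probands = proband, parents = parents, controls = controls,
       pedigree = ped, truth = truth, n_controls = cfg$n_controls)
}

#' Generate a case/control cohort for burden replicate studies
#'
#' Lightweight generator for the critical-exon burden machinery:
#' cases (`n_trios` individuals) and platform-matched controls
#' (`n_matched_controls`) each receive Poisson background CNVs over
#' the genome; with probability `effect` a case additionally
#' receives one CNV centered on a randomly chosen critical exon with
#' prenatal expression, planting carrier enrichment in the prenatal
#' strata only. `effect = 0` gives a null cohort.
#'
#' @param cfg a [sim_config()].
#' @param annotations bundle from [generate_annotations()].
#' @param effect per-case planting probability (default
#'   `cfg$burden_effect`).
#' @param seed integer seed.
#' @return list: case_cnvs, control_cnvs, n_cases, n_controls.
#' @export
generate_burden_cohort <- function(cfg = sim_config(),
                                   annotations = generate_annotations(cfg),
                                   effect = cfg$burden_effect, seed = 1) {
  set.seed(seed + 2L)
  cl <- annotations$chrom_lengths
  make_group <- function(ids) {
    n <- rpois(length(ids), cfg$cnv_rate)
    x <- random_cnvs(sum(n), cfg, cl)
    x$individual_id <- rep(ids, n)
    x[, c("individual_id", "chrom", "start", "end", "cnv_type")]
  }
  case_ids <- sprintf("CASE%03d", seq_len(cfg$n_trios))
  ctrl_ids <- sprintf("MCTL%04d", seq_len(cfg$n_matched_controls))
  cases <- make_group(case_ids)
  ctrls <- make_group(ctrl_ids)
  pre <- annotations$critical_exons[
    annotations$critical_exons$timepoint == "prenatal", , drop = FALSE]
  pre <- unique(pre[, c("chrom", "start", "end")])
  planted_in <- which(runif(cfg$n_trios) < effect)
  if (length(planted_in) && nrow(pre)) {
    tgt <- pre[sample.int(nrow(pre), length(planted_in), replace = TRUE), ]
    size <- round(exp(runif(length(planted_in), log(cfg$size_min_bp),
                            log(cfg$size_max_bp))))
    mid <- floor((tgt$start + tgt$end) / 2)
    start <- pmax(0, mid - floor(size / 2))
    planted <- data.frame(individual_id = case_ids[planted_in],
                          chrom = tgt$chrom, start = start,
                          end = pmin(start + size, cl[tgt$chrom]),
                          cnv_type = ifelse(runif(length(planted_in)) <
                                              cfg$del_fraction,
                                            "deletion", "duplication"),
                          stringsAsFactors = FALSE, row.names = NULL)
    cases <- rbind(cases, planted)
  }
  list(case_cnvs = cases, control_cnvs = ctrls,
       n_cases = cfg$n_trios, n_controls = cfg$n_matched_controls)
}
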