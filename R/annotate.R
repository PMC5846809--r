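#' Genes impacted by CNVs
#'
#' A gene is *impacted* by a CNV when the CNV intersects at least one
#' of its coding exons ("affects coding sequence"). CNVs overlapping
#' a gene body without touching a coding exon (intronic, UTR-only)
#' are reported with `coding_hit = FALSE` so noncoding contact can be
#' examined separately; downstream tiering and burden use only
#' `coding_hit = TRUE` records.
#'
#' @param cnvs CNV data.frame (one or more rows).
#' @param gene_models list from [read_gene_models()] (or the same
#'   shape from [generate_annotations()]).
#' @return data.frame: cnv_row, individual_id (when present),
#'   gene_symbol, n_coding_exons_hit, whole_gene, coding_hit.
#' @export
genes_impacted <- function(cnvs, gene_models) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  empty <- data.frame(cnv_row = integer(0), individual_id = character(0),
                      gene_symbol = character(0),
                      n_coding_exons_hit = integer(0),
                      whole_gene = logical(0), coding_hit = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(cnvs) == 0L || nrow(genes) == 0L) return(empty)
  ghits <- query_index(build_index(genes), cnvs)
  if (nrow(ghits) == 0L) return(empty)
  cod <- exons[exons$coding, , drop = FALSE]
  ehits <- if (nrow(cod)) query_index(build_index(cod), cnvs) else
    data.frame(gene_symbol = character(0), probe_row = integer(0))
  ekey <- paste(ehits$probe_row, ehits$gene_symbol)
  n_cod <- table(ekey)
  key <- paste(ghits$probe_row, ghits$gene_symbol)
  out <- data.frame(cnv_row = ghits$probe_row,
                    gene_symbol = ghits$gene_symbol,
                    n_coding_exons_hit = as.integer(ifelse(is.na(n_cod[key]),
                                                           0L, n_cod[key])),
                    stringsAsFactors = FALSE)
  out$whole_gene <- cnvs$start[out$cnv_row] <= ghits$start &
    cnvs$end[out$cnv_row] >= ghits$end
  out$coding_hit <- out$n_coding_exons_hit > 0L
  if (!is.null(cnvs$individual_id)) {
    out <- cbind(out[1], individual_id = cnvs$individual_id[out$cnv_row],
                 out[-1])
  }
  rownames(out) <- NULL
  out[order(out$cnv_row, out$gene_symbol), , drop = FALSE]
}

#' Genomic-disorder locus hits
#'
#' Reports curated syndrome loci (DECIPHER/ClinGen-style regions)
#' matched by a CNV at reciprocal overlap >= `ro_threshold`. The
#' reciprocal criterion requires the CNV to be size-congruent with
#' the locus, not merely to touch it.
#'
#' @param cnvs CNV data.frame.
#' @param syndrome_loci data.frame: locus, syndrome, chrom, start, end.
#' @param ro_threshold inclusive reciprocal-overlap threshold.
#' @return data.frame: cnv_row, locus, syndrome, ro.
#' @export
syndrome_hits <- function(cnvs, syndrome_loci, ro_threshold = 0.5) {
  empty <- data.frame(cnv_row = integer(0), locus = character(0),
                      syndrome = character(0), ro = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(cnvs) == 0L || nrow(syndrome_loci) == 0L) return(empty)
  hits <- query_index(build_index(syndrome_loci), cnvs)
  if (nrow(hits) == 0L) return(empty)
  ro <- reciprocal_overlap(cnvs[hits$probe_row, , drop = FALSE], hits)
  keep <- ro >= ro_threshold
  data.frame(cnv_row = hits$probe_row[keep], locus = hits$locus[keep],
             syndrome = hits$syndrome[keep], ro = ro[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign the clinical-relevance tier of a CNV
#'
#' Deterministic cascade: `T1_de_novo` for de novo or aneuploid
#' events; else `T2_syndrome_locus` for genomic-disorder locus
#' matches; else `T3_disease_gene_inherited` when an impacted gene is
#' on the disease-gene list; else `T4_other`. Biparental events are
#' treated as inherited.
#'
#' @param status inheritance status vector.
#' @param aneuploidy_flag logical vector.
#' @param has_syndrome_hit logical vector.
#' @param has_disease_gene logical vector.
#' @return character vector of tiers.
#' @export
assign_tier <- function(status, aneuploidy_flag, has_syndrome_hit,
                        has_disease_gene) {
  ifelse(status == "de_novo" | aneuploidy_flag, "T1_de_novo",
  ifelse(has_syndrome_hit, "T2_syndrome_locus",
  ifelse(has_disease_gene, "T3_disease_gene_inherited", "T4_other")))
}

#' Annotate inheritance-classified CNVs and assign tiers
#'
#' Attaches gene impacts, syndrome-locus hits, per-gene pLI scores
#' and the clinical tier to each rare CNV.
#'
#' @param calls output of [classify_trio_cnvs()] (CNV rows with
#'   `status` and `aneuploidy_flag`).
#' @param gene_models list from [read_gene_models()].
#' @param tracks annotation bundle from [read_annotation_tracks()] /
#'   [generate_annotations()].
#' @param cfg a [rarity_config()] (reused for the syndrome-locus
#'   reciprocal-overlap threshold).
#' @return list: `cnvs` (calls plus genes, n_genes, syndromes, tier
#'   columns), `gene_impacts` (with pLI), `syndrome_hits`.
#' @export
annotate_cnvs <- function(calls, gene_models, tracks, cfg = rarity_config()) {
  gi <- genes_impacted(calls, gene_models)
  gi$pli <- tracks$pli$pli[match(gi$gene_symbol, tracks$pli$gene_symbol)]
  sh <- syndrome_hits(calls, tracks$syndrome_loci, cfg$ro_threshold)
  coding <- gi[gi$coding_hit, , drop = FALSE]
  glist <- split(coding$gene_symbol, factor(coding$cnv_row,
                                            levels = seq_len(nrow(calls))))
  out <- calls
  out$genes <- vapply(glist, function(g) paste(sort(unique(g)), collapse = ","),
                      character(1))
  out$n_genes <- vapply(glist, function(g) length(unique(g)), integer(1))
  slist <- split(sh$syndrome, factor(sh$cnv_row, levels = seq_len(nrow(calls))))
  out$syndromes <- vapply(slist, function(s) paste(unique(s), collapse = ","),
                          character(1))
  dg <- tracks$disease_genes$gene_symbol
  hit_dg <- vapply(glist, function(g) any(g %in% dg), logical(1))
  an <- if (is.null(out$aneuploidy_flag)) rep(FALSE, nrow(out)) else
    out$aneuploidy_flag
  out$tier <- assign_tier(out$status, an, out$syndromes != "", hit_dg)
  list(cnvs = out, gene_impacts = gi, syndrome_hits = sh)
}

#' Per-individual pLI sums over deletion-impacted genes
#'
#' For each individual, sums pLI over the *set* of distinct genes
#' impacted by that individual's deletions (a gene hit by several
#' deletions counts once; duplications are excluded by default, per
#' the deletion/haploinsufficiency rationale of the pLI score).
#' Genes without a pLI entry contribute 0 and are returned in the
#' `missing_pli` attribute.
#'
#' @param gene_impacts data.frame with individual_id, gene_symbol,
#'   coding_hit and cnv_type (joinable from the annotated CNVs; the
#'   output of [annotate_cnvs()]`$gene_impacts` plus the CNV type —
#'   see [annotated_gene_impacts()]).
#' @param pli_table data.frame: gene_symbol, pli.
#' @param deletions_only restrict to deletion impacts (default TRUE).
#' @param individuals ids to report (zeros included); default the
#'   ids present in `gene_impacts`.
#' @return named numeric vector of pLI sums.
#' @export
pli_sums <- function(gene_impacts, pli_table, deletions_only = TRUE,
                     individuals = NULL) {
  x <- gene_impacts[gene_impacts$coding_hit, , drop = FALSE]
  if (deletions_only && !is.null(x$cnv_type)) {
    x <- x[x$cnv_type == "deletion", , drop = FALSE]
  }
  x <- unique(x[, c("individual_id", "gene_symbol")])
  x$pli <- pli_table$pli[match(x$gene_symbol, pli_table$gene_symbol)]
  missing <- sort(unique(x$gene_symbol[is.na(x$pli)]))
  x$pli[is.na(x$pli)] <- 0
  if (is.null(individuals)) individuals <- sort(unique(x$individual_id))
  sums <- setNames(numeric(length(individuals)), individuals)
  if (nrow(x)) {
    agg <- tapply(x$pli, x$individual_id, sum)
    sums[names(agg)] <- agg
  }
  attr(sums, "missing_pli") <- missing
  sums
}

#' Gene impacts joined with the CNV type of the parent call
#'
#' Convenience join: [annotate_cnvs()]`$gene_impacts` carries
#' `cnv_row`; this attaches `cnv_type` (and `status`) from the
#' annotated CNV table, the shape [pli_sums()] expects.
#'
#' @param annotated output list of [annotate_cnvs()].
#' @return gene-impact data.frame with cnv_type and status columns.
#' @export
annotated_gene_impacts <- function(annotated) {
  gi <- annotated$gene_impacts
  gi$cnv_type <- annotated$cnvs$cnv_type[gi$cnv_row]
  gi$status <- annotated$cnvs$status[gi$cnv_row]
  gi
}

## accept inheritance tokens as printed in clinical reports
normalize_status <- function(x) {
  key <- tolower(gsub("[ .]", "_", trimws(x)))
  map <- c(de_novo = "de_novo", denovo = "de_novo",
           maternal = "maternal", paternal = "paternal",
           biparental = "biparental",
           unknown_incomplete_trio = "unknown_incomplete_trio")
  out <- map[key]
  if (any(is.na(out))) {
    stop(sprintf("unknown inheritance token '%s'", x[is.na(out)][1]),
         call. = FALSE)
  }
  unname(out)
}

#' Cohort-level accounting of prioritized CNV events
#'
#' Builds the per-event report and the count summary for a set of
#' clinically prioritized CNVs: total events and distinct cases; de
#' novo events and cases (de novo status or aneuploid); inherited
#' events with the maternal/paternal split (biparental counted as
#' inherited but in neither split); and the headline cohort
#' proportions (cases with >= 1 de novo or aneuploid event, cases
#' with >= 1 inherited event, cases with any event, each over
#' `n_probands`).
#'
#' Works both on pipeline output ([annotate_cnvs()]`$cnvs`) and on
#' re-entered published event tables: `events` only needs
#' `individual_id` and `status` (tokens like "De novo", "Maternal"
#' are accepted), with optional `aneuploidy_flag` and `tier`.
#'
#' @param events data.frame of prioritized CNV events.
#' @param n_probands cohort size.
#' @return list: `report` (events with normalized status), `summary`
#'   (named list of counts and proportions).
#' @export
cohort_table <- function(events, n_probands) {
  if (nrow(events) == 0L) {
    return(list(report = events,
                summary = list(n_events = 0L, n_cases = 0L,
                               de_novo_events = 0L, de_novo_cases = 0L,
                               inherited_events = 0L, inherited_cases = 0L,
                               maternal_events = 0L, paternal_events = 0L,
                               prop_de_novo = 0, prop_inherited = 0,
                               prop_any = 0, tier_counts = integer(0))))
  }
  ev <- events
  ev$status <- normalize_status(ev$status)
  an <- if (is.null(ev$aneuploidy_flag)) rep(FALSE, nrow(ev)) else
    ev$aneuploidy_flag
  dn <- ev$status == "de_novo" | an
  inh <- ev$status %in% c("maternal", "paternal", "biparental")
  summary <- list(
    n_events = nrow(ev),
    n_cases = length(unique(ev$individual_id)),
    de_novo_events = sum(dn),
    de_novo_cases = length(unique(ev$individual_id[dn])),
    inherited_events = sum(inh),
    inherited_cases = length(unique(ev$individual_id[inh])),
    maternal_events = sum(ev$status == "maternal"),
    paternal_events = sum(ev$status == "paternal"),
    prop_de_novo = length(unique(ev$individual_id[dn])) / n_probands,
    prop_inherited = length(unique(ev$individual_id[inh])) / n_probands,
    prop_any = length(unique(ev$individual_id)) / n_probands,
    tier_counts = if (is.null(ev$tier)) integer(0) else
      table(ev$tier))
  list(report = ev, summary = summary)
}

#' Packaged example of a prioritized CNV event table
#'
#' Loads the event list of a published 97-trio hemiplegic cerebral
#' palsy cohort (30 prioritized CNVs in 23 cases) as re-entered from
#' the printed clinical summary: case label, individual id, sex, CNV
#' type, cytoband location, size in bp, gene annotation, inheritance
#' and an aneuploidy flag for the whole-chromosome event. Coordinates
#' are not part of the printed summary, so the table is consumed in
#' "pre-annotated" mode by [cohort_table()].
#'
#' @return data.frame of 30 events.
#' @export
example_cohort_events <- function() {
  path <- system.file("extdata", "cp_cohort_events.tsv", package = "hemicnv")
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$aneuploidy_flag <- as.logical(x$aneuploidy_flag)
  x
}
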