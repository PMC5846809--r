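test_that("gene impact requires coding-exon intersection", {
  gm <- tiny_gene_models()
  # CNV inside the first intron of GA: gene contact but no coding exon
  intronic <- cnv("P1", "1", 1150, 1350)
  gi <- genes_impacted(intronic, gm)
  expect_equal(nrow(gi[gi$coding_hit, ]), 0L)
  expect_equal(gi$gene_symbol, "GA")  # noncoding contact still reported
  # CNV spanning the whole 3-exon gene
  whole <- cnv("P1", "1", 900, 2100)
  gi <- genes_impacted(whole, gm)
  expect_equal(gi$n_coding_exons_hit, 3L)
  expect_true(gi$whole_gene)
  expect_true(gi$coding_hit)
  # no genes, no impacts
  expect_equal(nrow(genes_impacted(whole, list(
    genes = gm$genes[0, ], exons = gm$exons[0, ]))), 0L)
})

test_that("the 18p11 fixture duplication impacts LAMA1, PTPRM and LRRC30", {
  fix <- hg19_mini_annotations()
  gm <- list(genes = fix$genes, exons = fix$exons)
  dup <- cnv("CaseD", "18", 6900000, 6900000 + 1146375, "duplication")
  gi <- genes_impacted(dup, gm)
  expect_equal(sort(unique(gi$gene_symbol[gi$coding_hit])),
               c("LAMA1", "LRRC30", "PTPRM"))
  # the 67.6 kb 10p15.3 deletion hits at least two DIP2C exons
  del <- cnv("CaseF", "10", 500000, 500000 + 67632)
  gi <- genes_impacted(del, gm)
  expect_gte(gi$n_coding_exons_hit[gi$gene_symbol == "DIP2C"], 2L)
})

test_that("syndrome-locus hits require reciprocal size congruence", {
  loci <- hg19_mini_annotations()$syndrome_loci
  dup22 <- cnv("CaseG", "22", 18900000, 18900000 + 2548820, "duplication")
  h <- syndrome_hits(dup22, loci)
  expect_equal(h$locus, "22q11.21")
  expect_gte(h$ro, 0.5)
  del17 <- cnv("CaseH", "17", 14080000, 14080000 + 1395494)
  expect_equal(syndrome_hits(del17, loci)$locus, "17p12")
  # a small CNV inside the locus touches it but is not size-congruent
  small <- cnv("X", "22", 19000000, 19160405, "duplication")
  expect_equal(nrow(syndrome_hits(small, loci)), 0L)
  far <- cnv("Y", "5", 1e6, 2e6)
  expect_equal(nrow(syndrome_hits(far, loci)), 0L)
})

test_that("tier assignment follows the de novo > syndrome > disease-gene cascade", {
  expect_equal(assign_tier("de_novo", FALSE, TRUE, TRUE), "T1_de_novo")
  expect_equal(assign_tier("maternal", TRUE, FALSE, FALSE), "T1_de_novo")
  expect_equal(assign_tier("paternal", FALSE, TRUE, TRUE), "T2_syndrome_locus")
  expect_equal(assign_tier("maternal", FALSE, FALSE, TRUE),
               "T3_disease_gene_inherited")
  expect_equal(assign_tier("paternal", FALSE, FALSE, FALSE), "T4_other")
  # vectorized and order-independent
  st <- c("de_novo", "paternal", "maternal", "biparental")
  tiers <- assign_tier(st, c(FALSE, FALSE, FALSE, FALSE),
                       c(FALSE, TRUE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(tiers, c("T1_de_novo", "T2_syndrome_locus",
                        "T3_disease_gene_inherited", "T4_other"))
  expect_equal(rev(assign_tier(rev(st), rep(FALSE, 4),
                               c(FALSE, FALSE, TRUE, FALSE),
                               c(FALSE, TRUE, TRUE, TRUE))),
               assign_tier(st, rep(FALSE, 4),
                           c(FALSE, TRUE, FALSE, FALSE),
                           c(TRUE, TRUE, TRUE, FALSE)))
})

test_that("annotate_cnvs reproduces published-style tiering end to end", {
  fix <- hg19_mini_annotations()
  gm <- list(genes = fix$genes, exons = fix$exons)
  tracks <- c(fix["syndrome_loci"], fix["pli"],
              list(disease_genes = fix$disease_genes))
  calls <- rbind(cnv("CaseE", "6", 101900000, 101900000 + 475077),
                 cnv("CaseG", "22", 18900000, 18900000 + 2548820, "duplication"),
                 cnv("CaseQ", "7", 146500000, 146500000 + 114399))
  calls$status <- c("de_novo", "paternal", "maternal")
  calls$aneuploidy_flag <- FALSE
  ann <- annotate_cnvs(calls, gm, tracks)
  expect_equal(ann$cnvs$tier, c("T1_de_novo", "T2_syndrome_locus",
                                "T3_disease_gene_inherited"))
  expect_match(ann$cnvs$genes[1], "GRIK2")
  expect_match(ann$cnvs$genes[3], "CNTNAP2")
  expect_match(ann$cnvs$syndromes[2], "22q11.2")
})

test_that("pLI sums use set-of-genes semantics over deletions only", {
  pli <- data.frame(gene_symbol = c("G1", "G2", "G3"),
                    pli = c(0.98, 0.02, 0.5), stringsAsFactors = FALSE)
  gi <- data.frame(
    individual_id = c("A", "A", "A", "A", "B"),
    gene_symbol = c("G1", "G2", "G1", "G3", "G3"),
    coding_hit = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    cnv_type = c("deletion", "deletion", "deletion", "duplication", "deletion"),
    stringsAsFactors = FALSE)
  s <- pli_sums(gi, pli, individuals = c("A", "B"))
  # G1 hit by two deletions counts once; duplication-hit G3 excluded;
  # B's only contact is noncoding
  expect_equal(as.numeric(s), c(0.98 + 0.02, 0))
  # individuals with no deletions report 0
  expect_equal(as.numeric(pli_sums(gi[0, ], pli, individuals = "Z")), 0)
  # genes absent from the pLI table contribute 0 and are audited
  gi2 <- data.frame(individual_id = "A", gene_symbol = "NOVEL",
                    coding_hit = TRUE, cnv_type = "deletion")
  s2 <- pli_sums(gi2, pli)
  expect_equal(as.numeric(s2), 0)
  expect_equal(attr(s2, "missing_pli"), "NOVEL")
  # adding a deletion never decreases a sum
  gi3 <- rbind(gi, data.frame(individual_id = "A", gene_symbol = "G3",
                              coding_hit = TRUE, cnv_type = "deletion"))
  expect_gte(pli_sums(gi3, pli)[["A"]], s[["A"]])
})

test_that("cohort accounting matches the published 97-trio event table", {
  ev <- example_cohort_events()
  expect_equal(nrow(ev), 30L)
  ct <- cohort_table(ev, 97)
  s <- ct$summary
  expect_equal(s$n_events, 30L)
  expect_equal(s$n_cases, 23L)
  expect_equal(s$de_novo_events, 9L)
  expect_equal(s$de_novo_cases, 7L)
  expect_equal(s$inherited_events, 21L)
  expect_equal(s$maternal_events, 14L)
  expect_equal(s$paternal_events, 7L)
  expect_equal(round(100 * s$prop_de_novo, 1), 7.2)
  expect_equal(round(100 * s$prop_inherited, 1), 18.6)
  expect_equal(round(100 * s$prop_any, 1), 23.7)
})

test_that("cohort accounting is permutation invariant and handles empty input", {
  ev <- example_cohort_events()
  set.seed(3)
  shuffled <- ev[sample.int(nrow(ev)), ]
  expect_equal(cohort_table(shuffled, 97)$summary,
               cohort_table(ev, 97)$summary)
  empty <- cohort_table(ev[0, ], 97)
  expect_equal(empty$summary$n_events, 0L)
  expect_equal(empty$summary$prop_any, 0)
  expect_error(cohort_table(data.frame(individual_id = "A", status = "alien"),
                            10), "unknown inheritance token")
})
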