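# Small in-code fixtures and independent oracles shared across tests.

# one-line CNV row constructor (zero-length id gives an empty table)
cnv <- function(id, chrom, start, end, type = "deletion") {
  if (length(id) == 0L) {
    return(data.frame(individual_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      cnv_type = character(0), stringsAsFactors = FALSE))
  }
  data.frame(individual_id = id, chrom = as.character(chrom),
             start = start, end = end, cnv_type = type,
             stringsAsFactors = FALSE)
}

# brute-force reciprocal overlap of two single intervals
ro_brute <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
  min(ov / (a$end - a$start), ov / (b$end - b$start))
}

# brute-force all-pairs overlap scan (>= 1 bp), returns subject row indices
overlap_scan_brute <- function(probe, subjects) {
  which(subjects$chrom == probe$chrom &
        subjects$start < probe$end & subjects$end > probe$start)
}

# brute-force distinct-control carrier count
carrier_brute <- function(query, panel, cfg) {
  ok <- vapply(seq_len(nrow(panel)), function(j) {
    p <- panel[j, ]
    if (cfg$require_same_type && p$cnv_type != query$cnv_type) return(FALSE)
    ro_brute(query, p) >= cfg$ro_threshold
  }, logical(1))
  length(unique(panel$individual_id[ok]))
}

# hand step-up Benjamini-Hochberg, the textbook formula
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)
}

# random interval table on a small genome
random_intervals <- function(n, chroms = c("1", "2", "X"), max_pos = 1e6) {
  start <- floor(runif(n, 0, max_pos - 10))
  len <- pmax(1, floor(runif(n, 1, 5e4)))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# tiny deterministic gene model: one 3-exon gene + one single-exon gene
tiny_gene_models <- function() {
  genes <- data.frame(gene_symbol = c("GA", "GB"),
                      chrom = c("1", "2"),
                      start = c(1000, 5000), end = c(2000, 5500),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_symbol = c("GA", "GA", "GA", "GB"),
                      chrom = c("1", "1", "1", "2"),
                      start = c(1000, 1400, 1800, 5000),
                      end = c(1100, 1500, 2000, 5500),
                      exon_rank = c(1L, 2L, 3L, 1L),
                      coding = TRUE, stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}
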