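#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' in the package-internal convention: 0-based, half-open (`end`
#' exclusive), so that `end - start` is the length in bp. Chromosome
#' names are normalized by stripping an optional `"chr"` prefix;
#' mitochondrial and unplaced contig names pass through untouched.
#' CNVs are strandless, so no strand is carried anywhere.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open; `end > start`.
#' @param ... further equal-length columns attached as payload.
#' @return A data.frame of validated intervals.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  x <- data.frame(chrom = normalize_chrom(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  ...,
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` (any case); everything else (MT, unplaced
#' contigs) is passed through unchanged.
#'
#' @param x character vector.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Validate an interval table
#'
#' Checks the core interval invariants: required columns present,
#' non-negative starts, and `end > start` (minimum length 1 bp).
#'
#' @param x data.frame with `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(sprintf("%s table has missing coordinates", what), call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop(sprintf("%s table has negative start positions", what), call. = FALSE)
  }
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(sprintf("%s rows with end <= start (first at row %d)",
                 what, bad[1]), call. = FALSE)
  }
  invisible(x)
}

#' Interval lengths in bp
#'
#' @param x interval data.frame.
#' @return numeric vector `end - start`.
#' @export
interval_length <- function(x) {
  x$end - x$start
}

#' Reciprocal overlap of interval pairs
#'
#' The standard criterion for calling two CNV events "the same": the
#' minimum of the two intersection fractions,
#' `min(ov / len(a), ov / len(b))` where `ov` is the intersection
#' length. Returns 0 for different chromosomes or disjoint spans.
#' Symmetric in its arguments. Vectorized pairwise with recycling.
#'
#' @param a,b interval data.frames (1 row, or equal/recyclable lengths).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- genomic_intervals("1", 0, 100)
#' b <- genomic_intervals("1", 50, 150)
#' reciprocal_overlap(a, b)  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov <- pmax(ov, 0)
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  pmin(ov / (a$end[ai] - a$start[ai]), ov / (b$end[bi] - b$start[bi]))
}

#' Fraction of an interval covered by a union of regions
#'
#' Computes the fraction of `a`'s length covered by the union of
#' `regions` on the same chromosome; bases covered by several regions
#' are counted once. Used e.g. to require CNVs to lie mostly within
#' copy-number-stable genome.
#'
#' @param a a single-row interval data.frame.
#' @param regions interval data.frame (may be overlapping / unsorted).
#' @return a fraction in `[0, 1]`.
#' @examples
#' a <- genomic_intervals("1", 0, 100)
#' r <- genomic_intervals(c("1", "1"), c(0, 60), c(40, 100))
#' coverage_fraction(a, r)  # 0.8
#' @export
coverage_fraction <- function(a, regions) {
  validate_intervals(a, "probe")
  stopifnot(nrow(a) == 1L)
  if (nrow(regions) == 0L) return(0)
  validate_intervals(regions, "regions")
  r <- regions[regions$chrom == a$chrom, , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  s <- pmax(r$start, a$start)
  e <- pmin(r$end, a$end)
  keep <- e > s
  if (!any(keep)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = s[keep] + 1, end = e[keep]))))
  covered / (a$end - a$start)
}

## internal: interval data.frame -> GRanges (1-based closed for IRanges)
gi_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Build an overlap-query index over an interval table
#'
#' Wraps the interval table in a queryable index so downstream stages
#' (panel carrier counting, gene impact, critical-exon burden) can
#' retrieve all records intersecting a probe without an all-pairs scan.
#'
#' @param x interval data.frame with any payload columns.
#' @return an object of class `cnv_index`.
#' @seealso [query_index()]
#' @export
build_index <- function(x) {
  validate_intervals(x, "index input")
  structure(list(gr = gi_to_granges(x), data = x), class = "cnv_index")
}

#' @export
print.cnv_index <- function(x, ...) {
  cat(sprintf("<cnv_index: %d intervals on %d chromosome(s)>\n",
              nrow(x$data), length(unique(x$data$chrom))))
  invisible(x)
}

#' Query an overlap index
#'
#' Returns the indexed rows intersecting each probe interval by at
#' least one base, together with the probe row index (`probe_row`).
#' Equivalent to (and tested against) a brute-force all-pairs scan.
#'
#' @param index a `cnv_index` from [build_index()].
#' @param probe interval data.frame of one or more probes.
#' @return data.frame of hit rows with a `probe_row` column.
#' @export
query_index <- function(index, probe) {
  stopifnot(inherits(index, "cnv_index"))
  validate_intervals(probe, "probe")
  ## chromosome universes of probe and index may legitimately differ
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gi_to_granges(probe), index$gr))
  out <- index$data[S4Vectors::subjectHits(hits), , drop = FALSE]
  out$probe_row <- S4Vectors::queryHits(hits)
  rownames(out) <- NULL
  out
}

#' Read a BED track (BED3/BED6/BED12)
#'
#' Coordinates come back in the internal 0-based half-open convention
#' (identical to BED's own convention). BED12 block structure is
#' available through [read_gene_models()].
#'
#' @param path file path.
#' @return interval data.frame with `name`/`score` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  for (col in intersect(c("name", "score"), colnames(md))) {
    out[[col]] <- md[[col]]
  }
  validate_intervals(out, "BED")
  out
}

#' Write intervals as BED3/BED6
#'
#' @param x interval data.frame; a `name` column (and then `score`)
#'   upgrades the output to BED6-style columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED")
  cols <- data.frame(chrom = x$chrom,
                     start = format(x$start, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name)) {
    cols$name <- x$name
    cols$score <- if (is.null(x$score)) 0 else x$score
    cols$strand <- "."
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
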