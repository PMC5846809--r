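#' Brain region and developmental timepoint vocabularies
#'
#' The 16 brain-region abbreviations used for critical-exon burden
#' strata (AMY amygdaloid complex, CBC cerebellar cortex, V1C primary
#' visual cortex, STC caudal superior temporal cortex, IPC posterior
#' inferior parietal cortex, A1C primary auditory cortex, S1C primary
#' somatosensory cortex, M1C primary motor cortex, STR striatum, DFC
#' dorsolateral prefrontal cortex, MFC medial prefrontal cortex, VFC
#' ventrolateral prefrontal cortex, OFC orbital frontal cortex, MD
#' mediodorsal thalamus, ITC inferolateral temporal cortex, HIP
#' hippocampus) and the three developmental expression windows:
#' prenatal (12-37 weeks gestation), child_adolescent (4 months-15
#' years) and adult (>18 years).
#'
#' @return character vector of region codes / timepoint names.
#' @export
brain_regions <- function() {
  c("AMY", "CBC", "V1C", "STC", "IPC", "A1C", "S1C", "M1C",
    "STR", "DFC", "MFC", "VFC", "OFC", "MD", "ITC", "HIP")
}

#' @rdname brain_regions
#' @export
timepoints <- function() {
  c("prenatal", "child_adolescent", "adult")
}

## canonical type tokens accepted on input
.cnv_type_map <- c(del = "deletion", deletion = "deletion", DEL = "deletion",
                   dup = "duplication", duplication = "duplication",
                   DUP = "duplication")

normalize_cnv_type <- function(x, context = "cnv_type") {
  out <- .cnv_type_map[as.character(x)]
  if (any(is.na(out))) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unknown %s token '%s' at row %d (expect del/dup)",
                 context, as.character(x)[bad], bad), call. = FALSE)
  }
  unname(out)
}

#' Read a CNV call table
#'
#' Tab-separated with header; required columns `individual_id`,
#' `chrom`, `start`, `end`, `cnv_type` (tokens `del`/`dup`/
#' `deletion`/`duplication`); optional `copy_number_state` and
#' `source` are carried through. The `dialect` flag declares the
#' coordinate convention of the file; rows are converted to the
#' internal 0-based half-open convention on reading.
#'
#' @param path file path.
#' @param dialect `"zero_half_open"` (default, BED-like) or
#'   `"one_based_inclusive"` (array-reporting convention).
#' @return data.frame of validated CNV calls in internal coordinates.
#' @export
read_cnv_table <- function(path, dialect = c("zero_half_open", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("individual_id", "chrom", "start", "end", "cnv_type")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop(sprintf("CNV table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(individual_id = x$individual_id,
                    chrom = normalize_chrom(x$chrom),
                    start = as.numeric(x$start),
                    end = as.numeric(x$end),
                    cnv_type = if (nrow(x)) normalize_cnv_type(x$cnv_type) else character(0),
                    stringsAsFactors = FALSE)
  if (dialect == "one_based_inclusive") out$start <- out$start - 1
  if (!is.null(x$copy_number_state)) {
    out$copy_number_state <- as.integer(x$copy_number_state)
  }
  if (!is.null(x$source)) out$source <- x$source
  if (nrow(out)) validate_intervals(out, sprintf("CNV table %s", path))
  out
}

#' Write a CNV call table
#'
#' Inverse of [read_cnv_table()]; writing then reading with the same
#' dialect is the identity on the core columns.
#'
#' @param x CNV call data.frame in internal coordinates.
#' @param path output path.
#' @param dialect coordinate convention to write.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(x, path, dialect = c("zero_half_open", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  out <- x[, intersect(c("individual_id", "chrom", "start", "end", "cnv_type",
                         "copy_number_state", "source"), names(x)), drop = FALSE]
  if (dialect == "one_based_inclusive") out$start <- out$start + 1
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PED pedigree file
#'
#' Standard 6-column PED order: family_id, individual_id, father_id,
#' mother_id, sex (1 male / 2 female / 0 unknown), phenotype (2
#' affected = proband). Individuals referenced as a father or mother
#' get role `"parent"`; affected individuals get role `"proband"`.
#' A proband whose father or mother id is `"0"` (or does not resolve
#' within the family) is flagged `incomplete_trio`, and the dangling
#' reference is reported in the `warnings` attribute. Population
#' controls are supplied in a separate frequency panel, never as PED
#' rows.
#'
#' @param path file path (whitespace- or tab-separated, no header).
#' @return data.frame with columns family_id, individual_id,
#'   father_id, mother_id, sex, phenotype, role, incomplete_trio;
#'   attribute `warnings` lists dangling parent references.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(x) < 6) stop("PED file needs 6 columns", call. = FALSE)
  names(x)[1:6] <- c("family_id", "individual_id", "father_id",
                     "mother_id", "sex", "phenotype")
  x <- x[, 1:6]
  if (anyDuplicated(x$individual_id)) {
    stop(sprintf("duplicate individual id '%s' in %s",
                 x$individual_id[duplicated(x$individual_id)][1], path),
         call. = FALSE)
  }
  x$sex <- c(`1` = "male", `2` = "female", `0` = "unknown")[x$sex]
  x$sex[is.na(x$sex)] <- "unknown"
  is_parent <- x$individual_id %in% c(x$father_id, x$mother_id)
  x$role <- ifelse(x$phenotype == "2", "proband",
                   ifelse(is_parent, "parent", "other"))
  warnings <- character(0)
  x$incomplete_trio <- FALSE
  for (i in which(x$role == "proband")) {
    for (p in c("father_id", "mother_id")) {
      pid <- x[[p]][i]
      if (pid == "0" || !any(x$individual_id == pid & x$family_id == x$family_id[i])) {
        x$incomplete_trio[i] <- TRUE
        if (pid != "0") {
          warnings <- c(warnings, sprintf(
            "proband %s: %s '%s' not found in family %s",
            x$individual_id[i], p, pid, x$family_id[i]))
        }
      }
    }
  }
  attr(x, "warnings") <- warnings
  x
}

#' Write a PED pedigree file
#'
#' @param ped pedigree data.frame as returned by [read_pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(ped$family_id, ped$individual_id, ped$father_id,
                    ped$mother_id, sex, ped$phenotype)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models with exon structure
#'
#' Accepts BED12 (blocks become exons; the thick range marks the
#' coding span, exons overlapping it are flagged coding) or a
#' "GFF-lite" TSV with header columns gene_symbol, chrom, start, end,
#' feature (`gene`/`exon`), coding (0/1, exon rows). Coordinates in
#' the TSV follow `dialect` as in [read_cnv_table()]; BED12 is always
#' 0-based half-open.
#'
#' @param path file path.
#' @param format `"bed12"` or `"tsv"` (guessed from extension by default).
#' @param dialect coordinate dialect for the TSV format.
#' @return list with data.frames `genes` (gene_symbol, chrom, start,
#'   end) and `exons` (gene_symbol, chrom, start, end, exon_rank,
#'   coding).
#' @export
read_gene_models <- function(path, format = NULL,
                             dialect = c("zero_half_open", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  if (is.null(format)) {
    format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) "bed12" else "tsv"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(S4Vectors::mcols(gr)$blocks)) {
      stop("BED file has no block structure (need BED12)", call. = FALSE)
    }
    chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(gr)))
    genes <- data.frame(gene_symbol = S4Vectors::mcols(gr)$name,
                        chrom = chrom,
                        start = GenomicRanges::start(gr) - 1,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    bl <- rtracklayer::blocks(gr)
    n_ex <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    gidx <- rep(seq_along(gr), n_ex)
    exons <- data.frame(gene_symbol = genes$gene_symbol[gidx],
                        chrom = chrom[gidx],
                        start = GenomicRanges::start(flat) - 1,
                        end = GenomicRanges::end(flat),
                        stringsAsFactors = FALSE)
    exons$exon_rank <- unlist(lapply(n_ex, seq_len))
    thick <- S4Vectors::mcols(gr)$thick
    ts <- GenomicRanges::start(thick)[gidx] - 1
    te <- GenomicRanges::end(thick)[gidx]
    exons$coding <- pmin(exons$end, te) > pmax(exons$start, ts)
  } else {
    x <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_symbol", "chrom", "start", "end", "feature")
    miss <- setdiff(req, names(x))
    if (length(miss)) {
      stop(sprintf("gene model TSV lacks column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    x$chrom <- normalize_chrom(x$chrom)
    if (dialect == "one_based_inclusive") x$start <- x$start - 1
    genes <- x[x$feature == "gene",
               c("gene_symbol", "chrom", "start", "end")]
    exons <- x[x$feature == "exon",
               c("gene_symbol", "chrom", "start", "end")]
    exons$coding <- if (is.null(x$coding)) TRUE else
      as.logical(as.integer(x$coding[x$feature == "exon"]))
    exons <- exons[order(exons$gene_symbol, exons$start), ]
    exons$exon_rank <- stats::ave(exons$start, exons$gene_symbol,
                                  FUN = seq_along)
  }
  rownames(genes) <- rownames(exons) <- NULL
  validate_intervals(genes, "gene")
  validate_intervals(exons, "exon")
  ## exons must nest within their gene span
  gi <- match(exons$gene_symbol, genes$gene_symbol)
  if (any(is.na(gi)) ||
      any(exons$start < genes$start[gi] | exons$end > genes$end[gi])) {
    stop("exon outside its gene span (or orphan exon)", call. = FALSE)
  }
  list(genes = genes, exons = exons)
}

#' Read the annotation track bundle
#'
#' Loads the reference tracks used by filtering, tiering and burden:
#' copy-number-stable regions (BED), genomic-disorder ("syndrome")
#' loci (TSV: locus, syndrome, chrom, start, end), per-gene pLI
#' scores (TSV: gene_symbol, pli in \[0,1\]), critical exons (TSV:
#' chrom, start, end, gene_symbol, brain_region, timepoint; one row
#' per label) and a disease-gene list (TSV: gene_symbol, category).
#' Any path may be `NULL`, yielding an empty track.
#'
#' @param stable_regions,syndrome_loci,pli,critical_exons,disease_genes
#'   file paths (or `NULL`).
#' @param dialect coordinate dialect of the TSV tracks.
#' @return list of data.frames with the shapes described above.
#' @export
read_annotation_tracks <- function(stable_regions = NULL, syndrome_loci = NULL,
                                   pli = NULL, critical_exons = NULL,
                                   disease_genes = NULL,
                                   dialect = c("zero_half_open", "one_based_inclusive")) {
  dialect <- match.arg(dialect)
  shift <- if (dialect == "one_based_inclusive") 1 else 0
  tracks <- empty_annotation_tracks()
  if (!is.null(stable_regions)) tracks$stable_regions <- read_bed(stable_regions)
  if (!is.null(syndrome_loci)) {
    x <- read.delim(syndrome_loci, stringsAsFactors = FALSE)
    x$chrom <- normalize_chrom(x$chrom)
    x$start <- x$start - shift
    validate_intervals(x, "syndrome loci")
    tracks$syndrome_loci <- x
  }
  if (!is.null(pli)) {
    x <- read.delim(pli, stringsAsFactors = FALSE)
    if (any(x$pli < 0 | x$pli > 1, na.rm = TRUE)) {
      stop("pLI scores must lie in [0, 1]", call. = FALSE)
    }
    tracks$pli <- x
  }
  if (!is.null(critical_exons)) {
    x <- read.delim(critical_exons, stringsAsFactors = FALSE)
    x$chrom <- normalize_chrom(x$chrom)
    x$start <- x$start - shift
    validate_intervals(x, "critical exons")
    bad_region <- setdiff(unique(x$brain_region), brain_regions())
    if (length(bad_region)) {
      stop(sprintf("unknown brain region code(s): %s",
                   paste(bad_region, collapse = ", ")), call. = FALSE)
    }
    bad_tp <- setdiff(unique(x$timepoint), timepoints())
    if (length(bad_tp)) {
      stop(sprintf("unknown timepoint(s): %s",
                   paste(bad_tp, collapse = ", ")), call. = FALSE)
    }
    tracks$critical_exons <- x
  }
  if (!is.null(disease_genes)) {
    tracks$disease_genes <- read.delim(disease_genes, stringsAsFactors = FALSE)
  }
  tracks
}

#' @rdname read_annotation_tracks
#' @export
empty_annotation_tracks <- function() {
  list(stable_regions = data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)),
       syndrome_loci = data.frame(locus = character(0), syndrome = character(0),
                                  chrom = character(0), start = numeric(0),
                                  end = numeric(0)),
       pli = data.frame(gene_symbol = character(0), pli = numeric(0)),
       critical_exons = data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), gene_symbol = character(0),
                                   brain_region = character(0),
                                   timepoint = character(0)),
       disease_genes = data.frame(gene_symbol = character(0),
                                  category = character(0)))
}

#' Read a clinical covariate table
#'
#' TSV with header; must contain `individual_id`. All other columns
#' are covariates; the literal strings `"NA"`, `""` and `"missing"`
#' are treated as missing values.
#'
#' @param path file path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", "", "missing"))
  if (is.null(x$individual_id)) {
    stop("covariate table needs an individual_id column", call. = FALSE)
  }
  if (anyDuplicated(x$individual_id)) {
    stop("duplicate individual_id in covariate table", call. = FALSE)
  }
  x
}
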