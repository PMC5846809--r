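#' GRCh37/hg19 chromosome lengths
#'
#' Assembly lengths for chromosomes 1-22, X and Y, used to flag
#' whole-chromosome (aneuploid) events and to bound simulated CNVs.
#'
#' @return named numeric vector of lengths in bp.
#' @export
hg19_chrom_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' Flag whole-chromosome (aneuploid) CNVs
#'
#' TRUE iff the CNV spans more than `min_fraction` (default 90%) of
#' its chromosome. This separates whole-chromosome gains/losses
#' (e.g. an entire-X duplication in a 47,XXY individual) from large
#' segmental events (a 84.9 Mb Xq deletion covers only 55% of X and
#' is not flagged).
#'
#' @param cnv CNV data.frame (any number of rows).
#' @param chrom_lengths named lengths, default [hg19_chrom_lengths()].
#' @param min_fraction flag threshold, strict comparison.
#' @return logical vector.
#' @export
flag_aneuploidy <- function(cnv, chrom_lengths = hg19_chrom_lengths(),
                            min_fraction = 0.9) {
  len <- chrom_lengths[cnv$chrom]
  out <- interval_length(cnv) / len > min_fraction
  out[is.na(out)] <- FALSE
  unname(out)
}

#' Classify the inheritance of one proband CNV
#'
#' Matches the child CNV against each parent's CNV set using the same
#' reciprocal-overlap, same-type rule as the panel rarity filter
#' (reciprocal overlap >= `ro_threshold`). Status is `maternal` if
#' only the mother carries a match, `paternal` if only the father,
#' `biparental` if both, `de_novo` if neither, and
#' `unknown_incomplete_trio` when a parent's CNV data is missing
#' (pass `NULL` for that parent; an empty data.frame means
#' "genotyped, no CNVs").
#'
#' @param child_cnv single-row CNV data.frame.
#' @param mother_cnvs,father_cnvs CNV data.frames, or `NULL` when the
#'   parent was not genotyped.
#' @param cfg a [rarity_config()] (supplies `ro_threshold` and
#'   `require_same_type`).
#' @return one-row data.frame: status, best_parent_match_ro (NA when
#'   de novo or unknown), best_parent ("mother"/"father"/NA).
#' @export
classify_inheritance <- function(child_cnv, mother_cnvs, father_cnvs,
                                 cfg = rarity_config()) {
  stopifnot(nrow(child_cnv) == 1L)
  if (is.null(mother_cnvs) || is.null(father_cnvs)) {
    return(data.frame(status = "unknown_incomplete_trio",
                      best_parent_match_ro = NA_real_,
                      best_parent = NA_character_,
                      stringsAsFactors = FALSE))
  }
  best_ro <- function(parent_cnvs) {
    if (nrow(parent_cnvs) == 0L) return(0)
    p <- parent_cnvs
    if (cfg$require_same_type) {
      p <- p[p$cnv_type == child_cnv$cnv_type, , drop = FALSE]
      if (nrow(p) == 0L) return(0)
    }
    max(reciprocal_overlap(child_cnv, p))
  }
  ro_m <- best_ro(mother_cnvs)
  ro_f <- best_ro(father_cnvs)
  m <- ro_m >= cfg$ro_threshold
  f <- ro_f >= cfg$ro_threshold
  status <- if (m && f) "biparental" else if (m) "maternal" else
    if (f) "paternal" else "de_novo"
  data.frame(status = status,
             best_parent_match_ro = if (m || f) max(ro_m, ro_f) else NA_real_,
             best_parent = if (m && f) {
               if (ro_m >= ro_f) "mother" else "father"
             } else if (m) "mother" else if (f) "father" else NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify inheritance for a cohort of rare proband CNVs
#'
#' Joins each proband CNV with the parental CNV sets resolved through
#' the pedigree and applies [classify_inheritance()], adding the
#' aneuploidy flag. Parents listed in `genotyped_ids` but with no
#' rows in `parent_cnvs` count as genotyped-without-CNVs; parents
#' absent from `genotyped_ids` make the trio incomplete.
#'
#' @param rare_cnvs proband CNV data.frame (post rarity filter).
#' @param pedigree data.frame from [read_pedigree()].
#' @param parent_cnvs CNV data.frame for all parents.
#' @param cfg a [rarity_config()].
#' @param genotyped_ids individual ids with CNV data available;
#'   default: all ids appearing in `parent_cnvs`.
#' @param chrom_lengths for the aneuploidy flag.
#' @return `rare_cnvs` with columns status, best_parent_match_ro,
#'   best_parent, aneuploidy_flag appended.
#' @export
classify_trio_cnvs <- function(rare_cnvs, pedigree, parent_cnvs,
                               cfg = rarity_config(),
                               genotyped_ids = unique(parent_cnvs$individual_id),
                               chrom_lengths = hg19_chrom_lengths()) {
  out <- rare_cnvs
  out$status <- NA_character_
  out$best_parent_match_ro <- NA_real_
  out$best_parent <- NA_character_
  ped_idx <- match(rare_cnvs$individual_id, pedigree$individual_id)
  by_parent <- split(seq_len(nrow(parent_cnvs)), parent_cnvs$individual_id)
  parent_set <- function(pid) {
    if (is.na(pid) || pid == "0" || !(pid %in% genotyped_ids)) return(NULL)
    parent_cnvs[by_parent[[pid]] %||% integer(0), , drop = FALSE]
  }
  for (i in seq_len(nrow(rare_cnvs))) {
    pi <- ped_idx[i]
    mom <- if (is.na(pi)) NULL else parent_set(pedigree$mother_id[pi])
    dad <- if (is.na(pi)) NULL else parent_set(pedigree$father_id[pi])
    cls <- classify_inheritance(rare_cnvs[i, , drop = FALSE], mom, dad, cfg)
    out$status[i] <- cls$status
    out$best_parent_match_ro[i] <- cls$best_parent_match_ro
    out$best_parent[i] <- cls$best_parent
  }
  out$aneuploidy_flag <- flag_aneuploidy(rare_cnvs, chrom_lengths)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize de novo burden over a cohort
#'
#' Counts de novo events (status `de_novo` or aneuploid), the
#' distinct probands carrying at least one such event, and the cohort
#' proportion.
#'
#' @param calls data.frame with `individual_id`, `status` and
#'   optionally `aneuploidy_flag`.
#' @param n_probands cohort size (denominator).
#' @return list: `events`, `cases`, `proportion`.
#' @export
summarize_de_novo <- function(calls, n_probands) {
  an <- if (is.null(calls$aneuploidy_flag)) FALSE else calls$aneuploidy_flag
  hit <- calls$status == "de_novo" | an
  list(events = sum(hit),
       cases = length(unique(calls$individual_id[hit])),
       proportion = length(unique(calls$individual_id[hit])) / n_probands)
}
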