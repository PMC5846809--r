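#' Rarity filter configuration
#'
#' Thresholds for reducing proband CNV calls to rare, stringent
#' candidates:
#'
#' * `max_control_frequency` — a CNV is rare when the fraction of
#'   control individuals carrying a matching CNV is *not more than*
#'   this value (inclusive comparison); default 0.001 (0.1%).
#' * `ro_threshold` — two CNVs match when their reciprocal overlap is
#'   at least this fraction (inclusive); default 0.50.
#' * `stable_min_fraction` — the CNV must overlap copy-number-stable
#'   regions by *more than* this fraction (strict); default 0.75.
#' * `min_size_bp` — minimum CNV size; default 10 kb. There is no
#'   maximum: whole-chromosome events are legitimate candidates.
#' * `require_same_type` — only same-type events (del/del, dup/dup)
#'   match; default TRUE.
#'
#' @param max_control_frequency,ro_threshold,stable_min_fraction
#'   fractions in `[0, 1]`.
#' @param min_size_bp non-negative integer.
#' @param require_same_type flag.
#' @return a list of class `rarity_config`.
#' @export
rarity_config <- function(max_control_frequency = 0.001,
                          ro_threshold = 0.50,
                          stable_min_fraction = 0.75,
                          min_size_bp = 10000,
                          require_same_type = TRUE) {
  fr <- c(max_control_frequency, ro_threshold, stable_min_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (min_size_bp < 0) stop("min_size_bp must be >= 0", call. = FALSE)
  structure(list(max_control_frequency = max_control_frequency,
                 ro_threshold = ro_threshold,
                 stable_min_fraction = stable_min_fraction,
                 min_size_bp = min_size_bp,
                 require_same_type = isTRUE(require_same_type)),
            class = "rarity_config")
}

#' Count distinct control carriers of a CNV
#'
#' A control individual carries the query CNV when it has at least
#' one CNV of the same type (if `require_same_type`) whose reciprocal
#' overlap with the query reaches `ro_threshold`. An individual is
#' counted once regardless of how many of its CNVs match.
#'
#' @param cnv single-row CNV data.frame (with `cnv_type`).
#' @param panel_index control panel indexed with [build_index()]
#'   (payload must include `individual_id` and `cnv_type`), or a raw
#'   CNV data.frame (indexed on the fly).
#' @param cfg a [rarity_config()].
#' @return integer count of distinct carrier individuals.
#' @export
control_carrier_count <- function(cnv, panel_index, cfg = rarity_config()) {
  stopifnot(nrow(cnv) == 1L)
  if (is.data.frame(panel_index)) panel_index <- build_index(panel_index)
  hits <- query_index(panel_index, cnv)
  if (nrow(hits) == 0L) return(0L)
  if (cfg$require_same_type) {
    hits <- hits[hits$cnv_type == cnv$cnv_type, , drop = FALSE]
    if (nrow(hits) == 0L) return(0L)
  }
  ro <- reciprocal_overlap(cnv, hits)
  length(unique(hits$individual_id[ro >= cfg$ro_threshold]))
}

#' Is a carrier count rare in the panel?
#'
#' TRUE iff `count / n_controls <= max_control_frequency` ("not more
#' than" the cutoff, i.e. inclusive). With the defaults and a panel of
#' 10,851 individuals, a carrier count of 10 (0.0922%) passes and 11
#' (0.1014%) fails.
#'
#' @param count integer carrier count.
#' @param n_controls panel size (> 0).
#' @param cfg a [rarity_config()].
#' @return logical.
#' @export
is_rare <- function(count, n_controls, cfg = rarity_config()) {
  if (any(n_controls <= 0)) stop("n_controls must be positive", call. = FALSE)
  count / n_controls <= cfg$max_control_frequency
}

#' Does a CNV lie mostly within copy-number-stable regions?
#'
#' TRUE iff the union coverage of the CNV by the stable-region track
#' strictly exceeds `stable_min_fraction` ("more than" 75% with the
#' defaults; coverage exactly at the threshold fails).
#'
#' @param cnv single-row CNV data.frame.
#' @param stable_regions interval data.frame of stable regions.
#' @param cfg a [rarity_config()].
#' @return logical.
#' @export
stable_region_pass <- function(cnv, stable_regions, cfg = rarity_config()) {
  coverage_fraction(cnv, stable_regions) > cfg$stable_min_fraction
}

#' Filter proband CNVs to rare, stringent candidates
#'
#' Applies, in order, the minimum-size rule, the control-panel
#' frequency rule (distinct carrier individuals at reciprocal overlap
#' >= `ro_threshold`, same type), and the copy-number-stable region
#' rule. Every input CNV receives an audit record explaining the
#' decision, so the rejected set is partitioned by failure reason.
#'
#' @param proband_cnvs CNV data.frame (internal coordinates).
#' @param panel control CNV data.frame, or a prebuilt `cnv_index`.
#' @param stable_regions interval data.frame.
#' @param cfg a [rarity_config()].
#' @param n_controls number of individuals in the control panel;
#'   defaults to the number of distinct `individual_id`s in `panel`
#'   (supply explicitly when panel members without CNV calls exist).
#' @return list with `passed` (subset of input rows) and `audit`
#'   (one row per input CNV: size, carrier_count, control_frequency,
#'   stable_fraction, size_pass, rare_pass, stable_pass, pass,
#'   fail_reason).
#' @export
filter_rare_cnvs <- function(proband_cnvs, panel, stable_regions,
                             cfg = rarity_config(), n_controls = NULL) {
  if (is.data.frame(panel)) {
    if (is.null(n_controls)) n_controls <- length(unique(panel$individual_id))
    panel <- if (nrow(panel)) build_index(panel) else NULL
  } else if (is.null(n_controls)) {
    n_controls <- length(unique(panel$data$individual_id))
  }
  if (is.null(n_controls) || n_controls <= 0) {
    stop("n_controls must be positive", call. = FALSE)
  }
  n <- nrow(proband_cnvs)
  audit <- data.frame(individual_id = proband_cnvs$individual_id,
                      chrom = proband_cnvs$chrom,
                      start = proband_cnvs$start,
                      end = proband_cnvs$end,
                      cnv_type = proband_cnvs$cnv_type,
                      size_bp = interval_length(proband_cnvs),
                      carrier_count = NA_integer_,
                      control_frequency = NA_real_,
                      stable_fraction = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    row <- proband_cnvs[i, , drop = FALSE]
    audit$carrier_count[i] <- if (is.null(panel)) 0L else
      control_carrier_count(row, panel, cfg)
    audit$stable_fraction[i] <- coverage_fraction(row, stable_regions)
  }
  audit$control_frequency <- audit$carrier_count / n_controls
  audit$size_pass <- audit$size_bp >= cfg$min_size_bp
  audit$rare_pass <- is_rare(audit$carrier_count, n_controls, cfg)
  audit$stable_pass <- audit$stable_fraction > cfg$stable_min_fraction
  audit$pass <- audit$size_pass & audit$rare_pass & audit$stable_pass
  audit$fail_reason <- ifelse(audit$pass, "",
                       ifelse(!audit$size_pass, "size",
                       ifelse(!audit$rare_pass, "frequency", "unstable_region")))
  list(passed = proband_cnvs[audit$pass, , drop = FALSE], audit = audit)
}
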