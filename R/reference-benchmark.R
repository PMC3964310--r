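#' Reference interaction set
#'
#' A set of (bait, prey) gene-symbol pairs from a curated interaction
#' database, used to calibrate score thresholds. Symbols are uppercased and
#' duplicates collapsed.
#'
#' @param bait,prey character vectors of equal length
#' @param source_tag free-text provenance tag
#' @return a `reference_set` with a `pairs` data.frame
#' @export
reference_set <- function(bait, prey, source_tag = "") {
  pairs <- unique(data.frame(bait = toupper(bait), prey = toupper(prey),
                             stringsAsFactors = FALSE))
  structure(list(pairs = pairs, source_tag = source_tag), class = "reference_set")
}

#' Read a two-column (bait, prey) reference list from TSV
#' @param path file path; tab-delimited with header columns `bait`, `prey`
#' @param source_tag provenance tag stored on the set
#' @return a [reference_set()]
#' @export
read_reference_set <- function(path, source_tag = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("bait", "prey") %in% names(tab))) {
    stop("reference list needs 'bait' and 'prey' columns")
  }
  reference_set(tab$bait, tab$prey, source_tag)
}

#' Label scored pairs as known or novel
#'
#' A pair is *known* when it appears in the reference set (case-insensitive)
#' and *novel* otherwise. Absence from a reference database does not prove
#' non-interaction, so downstream false-positive rates are approximations.
#'
#' @param results a score table from [score_bait()]
#' @param ref a [reference_set()]
#' @return `results` with a logical `known` column
#' @export
label_results <- function(results, ref) {
  if (nrow(results) == 0L) stop("no scored results to label")
  key <- paste(results$bait, results$prey)
  results$known <- key %in% paste(ref$pairs$bait, ref$pairs$prey)
  results
}

#' ROC-like curve over a threshold grid
#'
#' At each threshold t, the approximate true-positive rate is the fraction
#' of known scored pairs with score >= t, the approximate false-positive
#' rate the fraction of novel scored pairs with score >= t, and recovery the
#' fraction of *all* reference pairs for the scored bait(s) passing at t
#' (reference pairs never observed with the bait count against recovery but
#' not against the rates).
#'
#' @param labeled a table from [label_results()]
#' @param ref the [reference_set()] used for labeling (recovery denominator)
#' @param grid thresholds in [0, 1]; sorted descending
#' @return a `roc_like` data.frame with columns `threshold`, `tp_rate`,
#'   `fp_rate`, `recovery`
#' @export
roc_like_curve <- function(labeled, ref, grid = seq(1, 0, by = -0.01)) {
  stopifnot(all(grid >= 0 & grid <= 1))
  grid <- sort(grid, decreasing = TRUE)
  n_known <- sum(labeled$known)
  n_novel <- sum(!labeled$known)
  if (n_known == 0L) warning("no known pairs among scored preys; TP-rate undefined")
  baits <- unique(labeled$bait)
  n_ref <- sum(ref$pairs$bait %in% baits)
  curve <- data.frame(
    threshold = grid,
    tp_rate = vapply(grid, function(t) {
      if (n_known == 0L) NA_real_ else sum(labeled$known & labeled$score >= t) / n_known
    }, numeric(1)),
    fp_rate = vapply(grid, function(t) {
      if (n_novel == 0L) NA_real_ else sum(!labeled$known & labeled$score >= t) / n_novel
    }, numeric(1)),
    recovery = vapply(grid, function(t) {
      if (n_ref == 0L) NA_real_ else sum(labeled$known & labeled$score >= t) / n_ref
    }, numeric(1))
  )
  ok <- !is.na(curve$tp_rate) & !is.na(curve$fp_rate)
  if (any(diff(curve$tp_rate[ok]) < 0) || any(diff(curve$fp_rate[ok]) < 0)) {
    stop("internal error: ROC-like rates not monotone over descending thresholds")
  }
  class(curve) <- c("roc_like", "data.frame")
  curve
}

#' Area under an ROC-like curve (trapezoid rule over FP-rate)
#' @param curve a [roc_like_curve()]
#' @return area in [0, 1], `NA` when rates are undefined
#' @export
roc_auc <- function(curve) {
  fp <- c(0, curve$fp_rate, 1)
  tp <- c(0, curve$tp_rate, 1)
  if (anyNA(fp) || anyNA(tp)) return(NA_real_)
  o <- order(fp, tp)
  sum(diff(fp[o]) * (utils::head(tp[o], -1) + utils::tail(tp[o], -1)) / 2)
}

#' Fraction of a bait's reference interactions recovered after filtering
#'
#' @param filtered a passing-results table from [apply_thresholds()]
#' @param ref a [reference_set()]
#' @param bait bait gene symbol
#' @return fraction in [0, 1], or `NA` (with a warning) when the bait has no
#'   reference pairs
#' @export
recovery_report <- function(filtered, ref, bait) {
  bait <- toupper(bait)
  ref_preys <- ref$pairs$prey[ref$pairs$bait == bait]
  if (length(ref_preys) == 0L) {
    warning("bait ", bait, " absent from the reference set; recovery undefined")
    return(NA_real_)
  }
  hits <- filtered$prey[filtered$bait == bait & filtered$passes]
  sum(ref_preys %in% hits) / length(ref_preys)
}
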