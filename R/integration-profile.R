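PROFILE_CATEGORIES <- c("stable", "dynamic", "rescued", "contaminant",
                        "nonspecific", "unquantified")

#' Thresholds for the specificity-by-stability classification
#'
#' @param saint_pass SAINT-score pass threshold for the bait (the same value
#'   used when filtering specific interactions)
#' @param stable_ratio I-DIRT ratio at or above which an interaction counts
#'   as stable (default 0.80)
#' @param contaminant_saint SAINT score below which a light-saturated prey
#'   is called an extrinsic contaminant (default 0.10)
#' @param contaminant_ratio I-DIRT ratio treated as "maximal" for the
#'   contaminant call (default 1.0, applied within `tol`)
#' @param tol numeric tolerance on the maximal-ratio comparison
#' @return a `profile_thresholds` list
#' @export
profile_thresholds <- function(saint_pass = 0.75, stable_ratio = 0.80,
                               contaminant_saint = 0.10,
                               contaminant_ratio = 1.0, tol = 1e-6) {
  structure(list(saint_pass = saint_pass, stable_ratio = stable_ratio,
                 contaminant_saint = contaminant_saint,
                 contaminant_ratio = contaminant_ratio, tol = tol),
            class = "profile_thresholds")
}

#' Join SAINT specificity and I-DIRT stability per prey
#'
#' Outer join on prey for one bait; a prey present in only one of the two
#' experiments keeps the other value missing (specific preys without I-DIRT
#' detection are not discarded).
#'
#' @param saint score table from [score_bait()] (optionally after
#'   [apply_thresholds()]; a `passes` column is carried through when present)
#' @param stab stability table from [protein_stability()]
#' @return data.frame with columns `bait`, `prey`, `saint_score`,
#'   `idirt_ratio` (plus `saint_passes` when available)
#' @export
join_profiles <- function(saint, stab) {
  baits <- unique(c(saint$bait, stab$bait))
  if (length(baits) > 1L) {
    stop("SAINT and I-DIRT tables are for different baits: ",
         paste(baits, collapse = ", "))
  }
  preys <- union(saint$prey, stab$prey)
  out <- data.frame(bait = rep(baits, length(preys)), prey = preys,
                    stringsAsFactors = FALSE)
  out$saint_score <- saint$score[match(preys, saint$prey)]
  if ("passes" %in% names(saint)) {
    out$saint_passes <- saint$passes[match(preys, saint$prey)]
    out$saint_passes[is.na(out$saint_passes)] <- FALSE
  }
  out$idirt_ratio <- stab$ratio[match(preys, stab$prey)]
  out
}

#' Classify one (SAINT score, I-DIRT ratio) pair
#'
#' The decision rules, applied in order (a missing SAINT score is treated as
#' 0 — no specificity evidence; see the package vignette):
#' \enumerate{
#'   \item `contaminant`: score < `contaminant_saint` and ratio >=
#'     `contaminant_ratio - tol` (light-saturated environmental protein);
#'   \item `rescued`: score below the pass threshold but ratio >=
#'     `stable_ratio` (stable by I-DIRT despite weak spectral-count
#'     evidence — a mitigated false negative);
#'   \item `stable`: passes SAINT and ratio >= `stable_ratio`;
#'   \item `dynamic`: passes SAINT and ratio < `stable_ratio`
#'     (fast-exchanging);
#'   \item `nonspecific`: fails SAINT with a sub-stable ratio;
#'   \item `unquantified`: passes SAINT but no I-DIRT ratio (specific on
#'     spectral-count evidence alone). A prey failing SAINT with no ratio is
#'     `nonspecific`.
#' }
#'
#' @param saint_score score in [0, 1] or `NA`
#' @param idirt_ratio ratio in [0, 1] or `NA`
#' @param cfg a [profile_thresholds()]
#' @return one of `r paste(PROFILE_CATEGORIES, collapse = ", ")`
#' @export
classify_profile <- function(saint_score, idirt_ratio, cfg = profile_thresholds()) {
  s <- if (is.na(saint_score)) 0 else saint_score
  passes <- s >= cfg$saint_pass
  if (is.na(idirt_ratio)) {
    return(if (passes) "unquantified" else "nonspecific")
  }
  r <- idirt_ratio
  if (s < cfg$contaminant_saint && r >= cfg$contaminant_ratio - cfg$tol) return("contaminant")
  if (!passes && r >= cfg$stable_ratio) return("rescued")
  if (passes && r >= cfg$stable_ratio) return("stable")
  if (passes) return("dynamic")
  "nonspecific"
}

#' Classify every joined profile
#'
#' @param profiles table from [join_profiles()]
#' @param cfg a [profile_thresholds()]; when the table carries a
#'   `saint_passes` column (per-bait thresholds already applied) that
#'   verdict overrides the plain `saint_pass` cutoff
#' @return `profiles` with a `category` factor column
#' @export
classify_profiles <- function(profiles, cfg = profile_thresholds()) {
  cat <- character(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    cfg_i <- cfg
    if ("saint_passes" %in% names(profiles)) {
      # encode an externally decided pass verdict via the threshold
      s <- profiles$saint_score[i]
      cfg_i$saint_pass <- if (isTRUE(profiles$saint_passes[i])) {
        if (is.na(s)) 0 else min(cfg$saint_pass, s)
      } else {
        Inf
      }
    }
    cat[i] <- classify_profile(profiles$saint_score[i], profiles$idirt_ratio[i], cfg_i)
  }
  profiles$category <- factor(cat, levels = PROFILE_CATEGORIES)
  profiles
}

#' Quadrant summary of classified profiles
#'
#' @param profiles table from [classify_profiles()]
#' @return list with `counts` (named integer vector over all categories,
#'   summing to `nrow(profiles)`), `total`, and `members` (per-category prey
#'   lists sorted by decreasing SAINT score); contaminants are counted but
#'   excluded from the `interactions` list
#' @export
quadrant_summary <- function(profiles) {
  counts <- table(factor(profiles$category, levels = PROFILE_CATEGORIES))
  ord <- order(-ifelse(is.na(profiles$saint_score), -1, profiles$saint_score))
  p <- profiles[ord, , drop = FALSE]
  members <- split(p$prey, factor(p$category, levels = PROFILE_CATEGORIES))
  interactions <- p$prey[!p$category %in% c("contaminant", "nonspecific")]
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total = nrow(profiles), members = members, interactions = interactions)
}
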