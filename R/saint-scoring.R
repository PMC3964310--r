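#' Configuration for the Poisson-mixture specificity scorer
#'
#' The scorer models each prey's (rounded, normalized) spectral count in a
#' bait run as a two-component Poisson mixture: a background component with
#' rate `lambda_false` estimated from the control runs, and a specific
#' component with rate `lambda_true` estimated from the bait's own
#' replicates. `pi_true` is the prior probability that a prey is a specific
#' interactor; the per-replicate probability (iProb) is the posterior of the
#' specific component given the count.
#'
#' @param pi_true prior probability of a specific interaction, in (0,1).
#' @param pseudocount smoothing count added to rate estimates.
#' @param minfold minimum fold of the background rate that the specific rate
#'   may take (the specific rate is floored at `lambda_false * minfold`).
#' @param min_separation small additive floor keeping `lambda_true`
#'   strictly above the floored background rate.
#' @return a `saint_config` list
#' @export
saint_config <- function(pi_true = 0.1, pseudocount = 0.1, minfold = 1,
                         min_separation = 1e-6) {
  stopifnot(pi_true > 0, pi_true < 1, pseudocount >= 0,
            minfold >= 0, min_separation > 0)
  structure(list(pi_true = pi_true, pseudocount = pseudocount,
                 minfold = minfold, min_separation = min_separation),
            class = "saint_config")
}

#' Background rate of a prey from the control runs
#'
#' Pseudocount-smoothed mean control count:
#' `(sum of control counts + pseudocount) / n_controls`.
#'
#' @param m a `normalized_counts` (or `count_matrix`)
#' @param prey prey gene symbol
#' @param pseudocount smoothing count
#' @return the background rate (counts/run)
#' @export
fit_background <- function(m, prey, pseudocount = 0.1) {
  ctrl <- runs_for_bait(m, CONTROL_BAIT)
  if (length(ctrl) == 0L) stop("no control runs present")
  prey <- toupper(prey)
  x <- if (prey %in% rownames(m$counts)) m$counts[prey, ctrl] else rep(0, length(ctrl))
  (sum(x) + pseudocount) / length(ctrl)
}

#' Per-replicate interaction probability (iProb)
#'
#' Posterior probability that a count was generated by the specific
#' component of the Poisson mixture:
#' `pi * P(k | lambda_true) / (pi * P(k | lambda_true) + (1 - pi) * P(k | lambda_false))`
#' with `P` the Poisson mass at `k = round(count)` (normalization makes
#' counts non-integral).
#'
#' @param count (normalized) spectral count, rounded to the nearest integer
#'   before evaluating the Poisson masses
#' @param lambda_false background rate (> 0 after smoothing)
#' @param lambda_true specific rate (> 0)
#' @param pi_true prior probability of a specific interaction
#' @return probability in [0, 1]
#' @export
score_replicate <- function(count, lambda_false, lambda_true, pi_true = 0.1) {
  if (!all(is.finite(c(count, lambda_false, lambda_true, pi_true)))) {
    stop("non-finite input to score_replicate")
  }
  stopifnot(lambda_false > 0, lambda_true > 0)
  k <- round(count)
  # log-space likelihood ratio for numerical stability at large counts
  llr <- stats::dpois(k, lambda_true, log = TRUE) -
    stats::dpois(k, lambda_false, log = TRUE)
  # posterior = 1 / (1 + prior-odds^-1 * LR^-1); this form cannot overflow
  inv_odds <- (1 - pi_true) / pi_true * exp(-llr)
  1 / (1 + inv_odds)
}

#' Combine replicate probabilities into the final score
#'
#' The final score of a bait-prey pair is the mean of the two highest
#' per-replicate probabilities, or the single probability when only one
#' replicate exists.
#'
#' @param iprobs numeric vector of per-replicate probabilities
#' @return final score in [0, 1]
#' @export
combine_iprobs <- function(iprobs) {
  iprobs <- iprobs[!is.na(iprobs)]
  if (length(iprobs) == 0L) return(NA_real_)
  if (length(iprobs) == 1L) return(iprobs)
  mean(sort(iprobs, decreasing = TRUE)[1:2])
}

#' Score all preys of one bait
#'
#' Modeling is per bait: the background rate of each prey comes from the
#' control runs and the specific rate from that bait's replicates only
#' (pseudocount-smoothed mean, floored at `lambda_false * minfold +
#' min_separation`), so the result is invariant to the presence of other
#' baits' runs. Only preys observed (count > 0) in at least one of the
#' bait's runs are scored; preys seen only in controls cannot be
#' interactions of the bait and are excluded.
#'
#' @param m a `normalized_counts` from [normalize_counts()] (a raw
#'   `count_matrix` is accepted)
#' @param bait bait gene symbol
#' @param config a [saint_config()]
#' @return data.frame with columns `bait`, `prey`, `iprob_1..k` (ordered by
#'   `replicate_index`), `n_rep`, `score`
#' @export
score_bait <- function(m, bait, config = saint_config()) {
  bait <- toupper(bait)
  brs <- m$runs[m$runs$bait == bait, , drop = FALSE]
  if (nrow(brs) == 0L) stop("no runs for bait ", bait)
  if (length(runs_for_bait(m, CONTROL_BAIT)) == 0L) stop("no control runs present")
  brs <- brs[order(brs$replicate_index), , drop = FALSE]
  bait_counts <- m$counts[, brs$run_id, drop = FALSE]
  observed <- rownames(bait_counts)[rowSums(bait_counts > 0) > 0]
  k <- nrow(brs)
  out <- data.frame(bait = rep(bait, length(observed)), prey = observed,
                    stringsAsFactors = FALSE)
  ip <- matrix(NA_real_, length(observed), k,
               dimnames = list(observed, paste0("iprob_", seq_len(k))))
  for (p in observed) {
    lf <- fit_background(m, p, config$pseudocount)
    lt_hat <- (sum(bait_counts[p, ]) + config$pseudocount) / k
    lt <- max(lt_hat, lf * config$minfold + config$min_separation)
    ip[p, ] <- vapply(bait_counts[p, ], score_replicate, numeric(1),
                      lambda_false = lf, lambda_true = lt,
                      pi_true = config$pi_true)
  }
  out <- cbind(out, as.data.frame(ip))
  out$n_rep <- k
  out$score <- apply(ip, 1L, combine_iprobs)
  rownames(out) <- NULL
  out
}

#' Per-bait score threshold policy
#'
#' @param default default threshold for baits without an explicit entry
#' @param default_strict logical; `FALSE` means pass at `score >= threshold`,
#'   `TRUE` means strict `score > threshold`
#' @param baits optional named list of per-bait entries, each a list with
#'   elements `threshold` and `strict`
#' @param manual_include optional data.frame of (bait, prey) pairs retained
#'   regardless of score (low-abundance interactors rescued by prior
#'   knowledge), flagged `manual = TRUE`
#' @return a `threshold_policy` list
#' @export
threshold_policy <- function(default = 0.75, default_strict = FALSE,
                             baits = list(), manual_include = NULL) {
  if (length(baits)) names(baits) <- toupper(names(baits))
  if (!is.null(manual_include)) {
    manual_include$bait <- toupper(manual_include$bait)
    manual_include$prey <- toupper(manual_include$prey)
  }
  structure(list(default = default, default_strict = default_strict,
                 baits = baits, manual_include = manual_include),
            class = "threshold_policy")
}

policy_for_bait <- function(policy, bait) {
  e <- policy$baits[[toupper(bait)]]
  if (is.null(e)) list(threshold = policy$default, strict = policy$default_strict)
  else list(threshold = e$threshold,
            strict = isTRUE(e$strict))
}

#' Apply per-bait score thresholds
#'
#' Marks each result as passing per its bait's threshold rule (`>=`, or `>`
#' when strict) and returns the annotated table. Manual-include pairs are
#' appended (or kept) with `passes = TRUE` and `manual = TRUE` even when
#' their score is below threshold.
#'
#' @param results a score table from [score_bait()] (rows from several baits
#'   may be concatenated)
#' @param policy a [threshold_policy()]
#' @param filter if `TRUE` (default) return only passing rows
#' @return the results with `threshold`, `strict`, `passes`, `manual`
#'   columns added
#' @export
apply_thresholds <- function(results, policy = threshold_policy(), filter = TRUE) {
  n <- nrow(results)
  results$threshold <- NA_real_
  results$strict <- NA
  results$passes <- FALSE
  results$manual <- FALSE
  for (i in seq_len(n)) {
    pe <- policy_for_bait(policy, results$bait[i])
    results$threshold[i] <- pe$threshold
    results$strict[i] <- pe$strict
    s <- results$score[i]
    results$passes[i] <- if (pe$strict) s > pe$threshold else s >= pe$threshold
  }
  mi <- policy$manual_include
  if (!is.null(mi) && nrow(mi)) {
    key <- paste(results$bait, results$prey)
    hit <- key %in% paste(mi$bait, mi$prey)
    results$passes[hit] <- TRUE
    results$manual[hit] <- TRUE
  }
  if (filter) results[results$passes, , drop = FALSE] else results
}
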