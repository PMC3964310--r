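#' Configuration for the synthetic AP-MS generator
#'
#' The generator emulates the statistical structure of a bait-vs-control
#' AP-MS study: a handful of bait cell lines each purified in 2-3 biological
#' replicates against a larger panel of control (tag-only) purifications,
#' spectral counts Poisson-distributed around per-prey rates, a minority of
#' preys specifically enriched with each bait (some shared across baits as
#' complex blocks), and SILAC peptide pairs whose light fraction is set by a
#' per-prey exchange fraction `f` (expected light fraction `1 - f/2`: a
#' non-exchanging, in-vivo-specific prey stays light-only at 1.0; a fully
#' exchanging prey equilibrates at 0.5).
#'
#' Defaults mirror the study design the pipeline targets: 3 replicates per
#' bait vs 7 controls, 50 specific preys per bait at rate 15 counts/run over
#' a 450-prey background at rates <= 0.5, 20 peptides per prey with
#' lognormal intensity noise (sigma 0.2), an equal-amount light/heavy mix,
#' and a small set of light-only environmental contaminants that dominate
#' control runs (rate 6) but are scarce in bait purifications (rate 1),
#' where the specific complex out-competes ambient background.
#'
#' @param n_baits number of bait cell lines
#' @param n_control_runs number of control purifications
#' @param n_replicates biological replicates per bait (2-3 typical)
#' @param n_background_preys size of the non-specific background panel
#' @param n_specific_per_bait specific interactors planted per bait
#' @param lambda_true spectral-count rate of a specific prey in its bait's runs
#' @param lambda_false_max background rates are drawn uniformly on
#'   (0.02, `lambda_false_max`)
#' @param shared_complex_size preys per shared-complex block (specific in
#'   every member bait); 0 disables
#' @param n_shared_complexes number of shared blocks (each shared by the
#'   first two baits)
#' @param exchange_fractions candidate exchange fractions `f` assigned to
#'   specific preys (recycled); `0` = stable, `1` = fully exchanging
#' @param peptides_per_prey SILAC peptide pairs quantified per prey
#' @param intensity_sigma lognormal sigma of per-peptide channel noise
#' @param mixing_imbalance realized light:heavy mixing ratio of the lysate
#'   mix (1 = equal amounts)
#' @param n_contaminants light-only environmental contaminant preys
#' @param contaminant_control_rate,contaminant_bait_rate their spectral-count
#'   rates in control and bait runs
#' @param n_input_proteins proteins quantified in the mixed-lysate input
#' @param overdispersion negative-binomial size parameter for robustness
#'   experiments; `Inf` (default) gives pure Poisson counts
#' @param seed mandatory RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_baits = 3, n_control_runs = 7, n_replicates = 3,
                       n_background_preys = 450, n_specific_per_bait = 50,
                       lambda_true = 15, lambda_false_max = 0.5,
                       shared_complex_size = 5, n_shared_complexes = 1,
                       exchange_fractions = c(0, 1),
                       peptides_per_prey = 20, intensity_sigma = 0.2,
                       mixing_imbalance = 1, n_contaminants = 10,
                       contaminant_control_rate = 6, contaminant_bait_rate = 1,
                       n_input_proteins = 30, overdispersion = Inf,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_baits >= 1, n_control_runs >= 1, n_replicates >= 1,
            lambda_true >= 0, lambda_false_max > 0,
            all(exchange_fractions >= 0 & exchange_fractions <= 1),
            mixing_imbalance > 0, intensity_sigma >= 0)
  structure(as.list(environment()), class = "sim_config")
}

rcounts <- function(n, rate, size) {
  if (is.infinite(size)) stats::rpois(n, rate) else stats::rnbinom(n, size = size, mu = rate)
}

#' Simulate a spectral-count matrix with planted truth
#'
#' Control counts are Poisson at each prey's background rate; bait counts
#' are Poisson at `lambda_true` for that bait's planted specific preys
#' (shared-complex preys are specific in all member baits) and at the
#' background rate otherwise. Contaminant preys use their own control/bait
#' rates. Protein lengths are uniform on 100-2000 aa and PAX-style cellular
#' abundances lognormal; both are returned as tables.
#'
#' @param cfg a [sim_config()]
#' @return list with `matrix` (a [count_matrix()]), `truth` (data.frame
#'   `prey`, `class` in background/specific/contaminant, `baits`
#'   (semicolon-joined), `exchange_fraction`), `lengths` and `pax`
#'   data.frames
#' @export
simulate_counts <- function(cfg) {
  set.seed(cfg$seed)
  baits <- sprintf("BAIT%d", seq_len(cfg$n_baits))
  n_shared <- cfg$n_shared_complexes * cfg$shared_complex_size
  shared_members <- if (cfg$n_baits >= 2 && n_shared > 0) baits[1:2] else character()
  if (length(shared_members) == 0) n_shared <- 0

  specific <- lapply(seq_len(cfg$n_baits), function(i) {
    n_own <- cfg$n_specific_per_bait -
      if (baits[i] %in% shared_members) n_shared else 0
    sprintf("SP%d_%03d", i, seq_len(max(n_own, 0)))
  })
  shared <- if (n_shared > 0) sprintf("SHC%03d", seq_len(n_shared)) else character()
  background <- sprintf("BG%03d", seq_len(cfg$n_background_preys))
  contaminants <- if (cfg$n_contaminants > 0)
    sprintf("CONT%02d", seq_len(cfg$n_contaminants)) else character()

  preys_gene <- c(unlist(specific), shared, background, contaminants)
  n_prey <- length(preys_gene)
  plen <- sample(100:2000, n_prey, replace = TRUE)
  preys <- data.frame(gene = preys_gene,
                      accession = sprintf("ACC%05d", seq_len(n_prey)),
                      length = plen, stringsAsFactors = FALSE)

  runs <- data.frame(
    run_id = c(sprintf("CTRL_%d", seq_len(cfg$n_control_runs)),
               unlist(lapply(baits, function(b) sprintf("%s_rep%d", b, seq_len(cfg$n_replicates))))),
    bait = c(rep(CONTROL_BAIT, cfg$n_control_runs),
             rep(baits, each = cfg$n_replicates)),
    replicate_index = c(seq_len(cfg$n_control_runs),
                        rep(seq_len(cfg$n_replicates), cfg$n_baits)),
    stringsAsFactors = FALSE
  )

  lambda_bg <- stats::runif(n_prey, 0.02, cfg$lambda_false_max)
  names(lambda_bg) <- preys_gene
  is_cont <- preys_gene %in% contaminants
  lambda_bg[is_cont] <- cfg$contaminant_control_rate

  # per-prey set of baits for which it is specific
  specific_for <- stats::setNames(vector("list", n_prey), preys_gene)
  for (i in seq_len(cfg$n_baits)) {
    for (g in specific[[i]]) specific_for[[g]] <- c(specific_for[[g]], baits[i])
  }
  for (g in shared) specific_for[[g]] <- shared_members

  counts <- matrix(0, n_prey, nrow(runs), dimnames = list(preys_gene, runs$run_id))
  for (j in seq_len(nrow(runs))) {
    b <- runs$bait[j]
    rate <- lambda_bg
    if (b != CONTROL_BAIT) {
      spec_here <- vapply(specific_for, function(s) b %in% s, logical(1))
      rate[spec_here] <- cfg$lambda_true
      rate[is_cont] <- cfg$contaminant_bait_rate
    }
    counts[, j] <- rcounts(n_prey, rate, cfg$overdispersion)
  }

  f_pool <- rep_len(cfg$exchange_fractions, sum(!is_cont & lengths(specific_for) > 0))
  truth <- data.frame(
    prey = preys_gene,
    class = ifelse(is_cont, "contaminant",
                   ifelse(lengths(specific_for) > 0, "specific", "background")),
    baits = vapply(specific_for, function(s) paste(s, collapse = ";"), character(1)),
    exchange_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
  truth$exchange_fraction[truth$class == "specific"] <- f_pool
  truth$exchange_fraction[truth$class == "contaminant"] <- 0  # light-only

  pax <- data.frame(gene = preys_gene,
                    abundance = stats::rlnorm(n_prey, meanlog = 3, sdlog = 1.2),
                    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(matrix = count_matrix(counts, preys, runs),
       truth = truth,
       lengths = preys[, c("gene", "length")],
       pax = pax)
}

#' Simulate SILAC peptide pairs for one bait's I-DIRT experiment
#'
#' For a prey with exchange fraction `f`, the expected light fraction of the
#' co-purified protein is `p = 1 - f/2` (an equal-amount light/heavy mix:
#' the exchanged portion re-equilibrates to 50:50 while the non-exchanged
#' portion stays light). Peptide intensities are drawn as
#' `L = B * p * m * exp(N(0, sigma))` and `H = B * (1 - p) * exp(N(0, sigma))`
#' with lognormal base abundance `B` and the configured mixing imbalance
#' `m`; `p = 1` yields exactly zero heavy signal. Contaminant preys are
#' emitted light-only. The input sample contains `n_input_proteins`
#' bystander proteins whose expected odds equal the mixing imbalance.
#'
#' @param cfg a [sim_config()]
#' @param truth truth table from [simulate_counts()]
#' @param bait bait gene symbol whose specific preys (plus contaminants) are
#'   quantified
#' @param seed optional seed (defaults to `cfg$seed + 1` so counts and
#'   peptides are independent draws)
#' @return list with `experiment` (an [idirt_experiment()]) and
#'   `truth` (data.frame `prey`, `exchange_fraction`, `expected_fraction`)
#' @export
simulate_peptides <- function(cfg, truth, bait, seed = cfg$seed + 1) {
  set.seed(seed)
  bait <- toupper(bait)
  in_ip <- (truth$class == "specific" &
              vapply(strsplit(truth$baits, ";"), function(b) bait %in% b, logical(1))) |
    truth$class == "contaminant"
  sel <- truth[in_ip, , drop = FALSE]
  m <- cfg$mixing_imbalance
  sig <- cfg$intensity_sigma

  gen_pairs <- function(genes, p_light, tag) {
    n_pep <- cfg$peptides_per_prey
    do.call(rbind, lapply(seq_along(genes), function(i) {
      B <- stats::rlnorm(n_pep, meanlog = 14, sdlog = 1)
      p <- p_light[i]
      L <- B * p * m * exp(stats::rnorm(n_pep, 0, sig))
      H <- B * (1 - p) * exp(stats::rnorm(n_pep, 0, sig))
      data.frame(prey = genes[i],
                 peptide_seq = sprintf("%s_%s_PEP%03d", tag, genes[i], seq_len(n_pep)),
                 light_intensity = L, heavy_intensity = H,
                 stringsAsFactors = FALSE)
    }))
  }

  p_exp <- 1 - sel$exchange_fraction / 2
  p_exp[sel$class == "contaminant"] <- 1  # light-only: no heavy channel at all
  pairs <- gen_pairs(sel$prey, p_exp, "IP")

  input_genes <- sprintf("INPUT%03d", seq_len(cfg$n_input_proteins))
  # input bystanders come half from each cell population: expected odds = m
  input_pairs <- gen_pairs(input_genes, rep(0.5, length(input_genes)), "IN")

  exp <- idirt_experiment(bait, pairs, input_pairs)
  list(experiment = exp,
       truth = data.frame(prey = sel$prey,
                          exchange_fraction = sel$exchange_fraction,
                          expected_fraction = p_exp,
                          stringsAsFactors = FALSE))
}

#' Simulate a reference interaction list from the planted truth
#'
#' @param truth truth table from [simulate_counts()]
#' @param coverage fraction of true (bait, prey) specific pairs included
#' @param noise number of spurious pairs added, as a fraction of the number
#'   of true pairs (preys drawn from the background panel)
#' @param seed RNG seed
#' @return a [reference_set()]
#' @export
simulate_reference <- function(truth, coverage = 1, noise = 0, seed = 1) {
  set.seed(seed)
  stopifnot(coverage >= 0, coverage <= 1, noise >= 0)
  spec <- truth[truth$class == "specific", , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    data.frame(bait = strsplit(spec$baits[i], ";")[[1]], prey = spec$prey[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) pairs <- data.frame(bait = character(), prey = character())
  n_take <- round(coverage * nrow(pairs))
  take <- if (n_take > 0) pairs[sample(nrow(pairs), n_take), , drop = FALSE] else
    pairs[0, , drop = FALSE]
  n_noise <- round(noise * nrow(pairs))
  if (n_noise > 0) {
    bg <- truth$prey[truth$class == "background"]
    baits <- unique(pairs$bait)
    take <- rbind(take, data.frame(
      bait = sample(baits, n_noise, replace = TRUE),
      prey = sample(bg, n_noise, replace = n_noise > length(bg)),
      stringsAsFactors = FALSE))
  }
  reference_set(take$bait, take$prey, source_tag = "synthetic-truth")
}

#' Write all synthetic tables of one simulation to a directory
#'
#' Emits `counts.tsv` (long dialect), `reference.tsv`, `lengths.tsv`,
#' `pax.tsv`, `truth.tsv`, and one `peptides_<bait>.tsv` per bait.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_simulation <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(cfg)
  paths <- c(counts = file.path(out_dir, "counts.tsv"))
  write_count_matrix(sim$matrix, paths["counts"])
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  ref <- simulate_reference(sim$truth, coverage = 1, noise = 0, seed = cfg$seed + 2)
  paths["reference"] <- wt(ref$pairs, "reference.tsv")
  paths["lengths"] <- wt(sim$lengths, "lengths.tsv")
  paths["pax"] <- wt(sim$pax, "pax.tsv")
  paths["truth"] <- wt(sim$truth, "truth.tsv")
  baits <- setdiff(unique(sim$matrix$runs$bait), CONTROL_BAIT)
  for (b in baits) {
    pep <- simulate_peptides(cfg, sim$truth, b)
    ip <- cbind(pep$experiment$pairs, sample = "ip")
    input <- cbind(pep$experiment$input_pairs, sample = "input")
    names(ip)[1] <- names(input)[1] <- "prey_gene"
    paths[paste0("peptides_", b)] <- wt(rbind(ip, input),
                                        paste0("peptides_", b, ".tsv"))
  }
  invisible(paths)
}
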