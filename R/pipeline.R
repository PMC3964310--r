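#' Default pipeline configuration
#'
#' One nested list drives the whole workflow; it can equally be loaded from
#' a YAML file with [read_pipeline_config()]. Thresholds default to the
#' pipeline's standard policy: SAINT pass at 0.75 (per-bait overrides
#' possible, e.g. 0.90 for promiscuous class I baits or a strict 0.95),
#' stable/dynamic boundary at an I-DIRT ratio of 0.80, contaminant
#' signature at SAINT < 0.10 with ratio 1.0.
#'
#' @param seed seed for every stochastic stage
#' @return nested configuration list
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(enabled = TRUE),
    saint = list(pi_true = 0.1, pseudocount = 0.1, minfold = 1, normalize = TRUE,
                 threshold = 0.75, strict = FALSE, per_bait = list()),
    benchmark = list(enabled = TRUE, coverage = 1, noise = 0),
    idirt = list(enabled = TRUE),
    integrate = list(stable_ratio = 0.80, contaminant_saint = 0.10,
                     contaminant_ratio = 1.0),
    cluster = list(enabled = TRUE),
    enrich = list(enabled = TRUE, reference_prey = NULL),
    network = list(enabled = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are a configuration error; missing blocks fall
#' back to [default_pipeline_config()] values.
#'
#' @param path YAML file path
#' @return nested configuration list
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("configuration error: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(base[[k]]) && is.list(cfg[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(base[[k]]))
      if (length(bad)) stop("configuration error: unknown field(s): ",
                            paste(paste0(k, ".", bad), collapse = ", "))
      base[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      base[[k]] <- cfg[[k]]
    }
  }
  base
}

manifest_entry <- function(stage, paths) {
  data.frame(stage = stage, file = basename(paths),
             digest = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Run the full hybrid AP-MS workflow
#'
#' Stages, in dependency order: `simulate` (synthetic inputs), `saint`
#' (per-bait normalization + mixture scoring + thresholds), `benchmark`
#' (ROC-like calibration against the reference list), `idirt` (stability
#' ratios per bait), `integrate` (quadrant classification), `cluster`
#' (hierarchical clustering of passing preys), `enrich` (NSAF / abundance
#' enrichment indices), `network` (node/edge export). Each stage writes TSV
#' outputs under `out_dir` and records an md5 digest in the run manifest;
#' with `resume = TRUE`, a stage whose recorded outputs all exist with
#' matching digests is skipped, and a mismatching digest is a dependency
#' error (no silent overwrite).
#'
#' @param config nested list from [default_pipeline_config()] /
#'   [read_pipeline_config()], or a YAML path
#' @param out_dir output directory
#' @param stages character vector of stage names to run (default all
#'   enabled)
#' @param resume skip stages whose outputs match the existing manifest
#' @return the run manifest (data.frame), invisibly; also written to
#'   `manifest.tsv` with the config echoed to `config.yaml`
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         stages = c("simulate", "saint", "benchmark", "idirt",
                                    "integrate", "cluster", "enrich", "network"),
                         resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  old_manifest <- if (resume && file.exists(manifest_path)) {
    utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  } else NULL
  manifest <- data.frame(stage = character(), file = character(),
                         digest = character(), stringsAsFactors = FALSE)
  t0 <- Sys.time()
  log <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)))

  stage_done <- function(stage, paths) {
    manifest <<- rbind(manifest, manifest_entry(stage, paths))
  }
  stage_cached <- function(stage) {
    if (is.null(old_manifest)) return(FALSE)
    rec <- old_manifest[old_manifest$stage == stage, , drop = FALSE]
    if (nrow(rec) == 0L) return(FALSE)
    paths <- file.path(out_dir, rec$file)
    if (!all(file.exists(paths))) return(FALSE)
    now <- unname(tools::md5sum(paths))
    if (!identical(now, rec$digest)) {
      stop("dependency error: outputs of stage '", stage,
           "' changed since the recorded manifest; refusing to overwrite")
    }
    manifest <<- rbind(manifest, rec)
    TRUE
  }
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  sim_cfg <- sim_config(seed = config$seed)
  scfg <- saint_config(pi_true = config$saint$pi_true,
                       pseudocount = config$saint$pseudocount,
                       minfold = config$saint$minfold)
  per_bait <- lapply(config$saint$per_bait, function(e) {
    list(threshold = e$threshold, strict = isTRUE(e$strict))
  })
  policy <- threshold_policy(default = config$saint$threshold,
                             default_strict = isTRUE(config$saint$strict),
                             baits = per_bait)

  # --- simulate -------------------------------------------------------------
  if ("simulate" %in% stages && isTRUE(config$simulate$enabled)) {
    if (!(resume && stage_cached("simulate"))) {
      log("simulate: generating synthetic AP-MS inputs (seed %d)", config$seed)
      paths <- write_simulation(sim_cfg, out_dir)
      stage_done("simulate", paths)
    } else log("simulate: cached")
  }
  counts_path <- file.path(out_dir, "counts.tsv")
  if (!file.exists(counts_path)) {
    stop("dependency error: missing upstream file ", counts_path)
  }
  m <- read_count_matrix(counts_path, "long")
  m <- zero_bait_self_counts(clean_preys(m))
  truth_path <- file.path(out_dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  } else NULL
  baits <- setdiff(unique(m$runs$bait), CONTROL_BAIT)

  # --- saint ----------------------------------------------------------------
  if ("saint" %in% stages) {
    if (!(resume && stage_cached("saint"))) {
      log("saint: scoring %d bait(s) against %d control run(s)",
          length(baits), length(runs_for_bait(m, CONTROL_BAIT)))
      scored <- do.call(rbind, lapply(baits, function(b) {
        mb <- if (isTRUE(config$saint$normalize)) normalize_counts(m, b) else m
        score_bait(mb, b, scfg)
      }))
      annotated <- apply_thresholds(scored, policy, filter = FALSE)
      stage_done("saint", c(wt(annotated, "saint_results.tsv")))
    } else log("saint: cached")
  }
  saint_path <- file.path(out_dir, "saint_results.tsv")

  # --- benchmark ------------------------------------------------------------
  if ("benchmark" %in% stages && isTRUE(config$benchmark$enabled)) {
    if (!file.exists(saint_path)) stop("dependency error: missing upstream file ", saint_path)
    if (!(resume && stage_cached("benchmark"))) {
      scored <- utils::read.delim(saint_path, stringsAsFactors = FALSE)
      ref_path <- file.path(out_dir, "reference.tsv")
      if (!file.exists(ref_path)) stop("dependency error: missing upstream file ", ref_path)
      ref <- read_reference_set(ref_path)
      curves <- do.call(rbind, lapply(baits, function(b) {
        lab <- label_results(scored[scored$bait == b, ], ref)
        cv <- roc_like_curve(lab, ref)
        cbind(bait = b, cv, auc = roc_auc(cv))
      }))
      log("benchmark: ROC-like curves for %d bait(s), mean AUC %.3f",
          length(baits), mean(unique(curves$auc)))
      stage_done("benchmark", wt(curves, "roc_curves.tsv"))
    } else log("benchmark: cached")
  }

  # --- idirt ----------------------------------------------------------------
  if ("idirt" %in% stages && isTRUE(config$idirt$enabled)) {
    if (!(resume && stage_cached("idirt"))) {
      stab <- do.call(rbind, lapply(baits, function(b) {
        pep_path <- file.path(out_dir, paste0("peptides_", b, ".tsv"))
        if (!file.exists(pep_path)) stop("dependency error: missing upstream file ", pep_path)
        protein_stability(read_peptide_table(pep_path, b))
      }))
      log("idirt: %d protein stability ratio(s)", nrow(stab))
      stage_done("idirt", wt(stab, "stability.tsv"))
    } else log("idirt: cached")
  }
  stab_path <- file.path(out_dir, "stability.tsv")

  # --- integrate ------------------------------------------------------------
  if ("integrate" %in% stages) {
    for (p in c(saint_path, stab_path)) {
      if (!file.exists(p)) stop("dependency error: missing upstream file ", p)
    }
    if (!(resume && stage_cached("integrate"))) {
      scored <- utils::read.delim(saint_path, stringsAsFactors = FALSE)
      stab <- utils::read.delim(stab_path, stringsAsFactors = FALSE)
      profiles <- do.call(rbind, lapply(baits, function(b) {
        prof <- join_profiles(scored[scored$bait == b, ], stab[stab$bait == b, ])
        classify_profiles(prof, profile_thresholds(
          saint_pass = policy_for_bait(policy, b)$threshold,
          stable_ratio = config$integrate$stable_ratio,
          contaminant_saint = config$integrate$contaminant_saint,
          contaminant_ratio = config$integrate$contaminant_ratio))
      }))
      qs <- quadrant_summary(profiles)
      log("integrate: %s", paste(names(qs$counts), qs$counts, sep = "=", collapse = " "))
      stage_done("integrate", wt(profiles, "profiles.tsv"))
    } else log("integrate: cached")
  }
  profiles_path <- file.path(out_dir, "profiles.tsv")

  # --- cluster --------------------------------------------------------------
  if ("cluster" %in% stages && isTRUE(config$cluster$enabled)) {
    if (!file.exists(saint_path)) stop("dependency error: missing upstream file ", saint_path)
    if (!(resume && stage_cached("cluster"))) {
      scored <- utils::read.delim(saint_path, stringsAsFactors = FALSE)
      passing <- unique(scored$prey[scored$passes])
      sub <- m$counts[rownames(m$counts) %in% passing, , drop = FALSE]
      cl <- cluster_matrix(sub)
      hm <- wt(data.frame(prey = rownames(cl$matrix), cl$matrix,
                          check.names = FALSE), "cluster_matrix.tsv")
      nw1 <- file.path(out_dir, "prey_dendrogram.nwk")
      nw2 <- file.path(out_dir, "run_dendrogram.nwk")
      write_dendrogram_newick(cl$prey_hclust, nw1)
      write_dendrogram_newick(cl$run_hclust, nw2)
      log("cluster: %d passing preys over %d runs", nrow(sub), ncol(sub))
      stage_done("cluster", c(hm, nw1, nw2))
    } else log("cluster: cached")
  }

  # --- enrich ---------------------------------------------------------------
  if ("enrich" %in% stages && isTRUE(config$enrich$enabled)) {
    if (!file.exists(saint_path)) stop("dependency error: missing upstream file ", saint_path)
    if (!(resume && stage_cached("enrich"))) {
      scored <- utils::read.delim(saint_path, stringsAsFactors = FALSE)
      pax_path <- file.path(out_dir, "pax.tsv")
      if (!file.exists(pax_path)) stop("dependency error: missing upstream file ", pax_path)
      pax <- utils::read.delim(pax_path, stringsAsFactors = FALSE)
      enr <- do.call(rbind, lapply(baits, function(b) {
        passing <- scored$prey[scored$bait == b & scored$passes]
        if (length(passing) < 1L) return(NULL)
        runs <- runs_for_bait(m, b)
        mean_counts <- rowMeans(m$counts[passing, runs, drop = FALSE])
        lens <- m$preys$length[match(passing, m$preys$gene)]
        ns <- nsaf(mean_counts, lens)
        ref_prey <- config$enrich$reference_prey
        if (is.null(ref_prey)) ref_prey <- names(sort(ns, decreasing = TRUE))[1]
        cbind(bait = b,
              enrichment_index(ns, stats::setNames(pax$abundance, pax$gene), ref_prey))
      }))
      log("enrich: %d enrichment record(s)", nrow(enr))
      stage_done("enrich", wt(enr, "enrichment.tsv"))
    } else log("enrich: cached")
  }

  # --- network --------------------------------------------------------------
  if ("network" %in% stages && isTRUE(config$network$enabled)) {
    if (!file.exists(profiles_path)) stop("dependency error: missing upstream file ", profiles_path)
    if (!(resume && stage_cached("network"))) {
      profiles <- utils::read.delim(profiles_path, stringsAsFactors = FALSE)
      net <- export_network(profiles, counts = m)
      paths <- write_network(net, file.path(out_dir, "network"))
      log("network: %d node(s), %d edge(s)", nrow(net$nodes), nrow(net$edges))
      stage_done("network", paths)
    } else log("network: cached")
  }

  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(manifest, "seed") <- config$seed
  attr(manifest, "config_digest") <- unname(tools::md5sum(cfg_path))
  attr(manifest, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  invisible(manifest)
}
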