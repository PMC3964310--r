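#' I-DIRT experiment container
#'
#' Holds SILAC peptide-pair quantifications from one isotope-labeled
#' purification: in the I-DIRT design, cells expressing the tagged bait are
#' grown in light medium and wild-type cells in heavy medium, the two
#' populations are mixed in equal amounts before lysis, and the light
#' fraction of each co-purified protein reports how far it exchanged between
#' the pools during isolation (~0.5 fully exchanging, 1.0 stable and
#' in-vivo specific).
#'
#' @param bait bait gene symbol
#' @param pairs data.frame of IP peptide pairs with columns `prey`,
#'   `peptide_seq`, `light_intensity`, `heavy_intensity`
#' @param input_pairs data.frame of the same shape from the mixed-lysate
#'   input sample, used to estimate the actual mixing ratio; may be `NULL`
#'   to disable normalization
#' @return an `idirt_experiment`
#' @export
idirt_experiment <- function(bait, pairs, input_pairs = NULL) {
  check <- function(p, what) {
    need <- c("prey", "peptide_seq", "light_intensity", "heavy_intensity")
    if (!all(need %in% names(p))) {
      stop(what, " needs columns: ", paste(need, collapse = ", "))
    }
    if (any(p$light_intensity < 0) || any(p$heavy_intensity < 0)) {
      stop("negative intensity in ", what)
    }
    p$prey <- toupper(p$prey)
    both_zero <- p$light_intensity == 0 & p$heavy_intensity == 0
    if (any(both_zero)) {
      warning("skipping ", sum(both_zero), " ", what,
              " peptide(s) with zero intensity in both channels")
      p <- p[!both_zero, , drop = FALSE]
    }
    # peptides assigned to more than one prey are ambiguous; drop all copies
    multi <- vapply(split(p$prey, p$peptide_seq), function(g) length(unique(g)) > 1,
                    logical(1))
    shared <- names(multi)[multi]
    if (length(shared)) {
      warning("dropping ", length(shared), " shared peptide(s) mapping to multiple preys")
      p <- p[!(p$peptide_seq %in% shared), , drop = FALSE]
    }
    p
  }
  pairs <- check(as.data.frame(pairs), "IP")
  if (!is.null(input_pairs)) input_pairs <- check(as.data.frame(input_pairs), "input")
  structure(list(bait = toupper(bait), pairs = pairs, input_pairs = input_pairs),
            class = "idirt_experiment")
}

#' Read an I-DIRT peptide table
#'
#' Tab-delimited with columns `prey_gene`, `peptide_seq`, `light_intensity`,
#' `heavy_intensity`, `sample` (`ip` or `input`); `#` comment lines ignored.
#'
#' @param path file path
#' @param bait bait gene symbol
#' @return an [idirt_experiment()]
#' @export
read_peptide_table <- function(path, bait) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("prey_gene", "peptide_seq", "light_intensity", "heavy_intensity", "sample")
  if (!all(need %in% names(tab))) {
    stop("peptide table needs columns: ", paste(need, collapse = ", "))
  }
  names(tab)[names(tab) == "prey_gene"] <- "prey"
  ip <- tab[tab$sample == "ip", c("prey", "peptide_seq", "light_intensity", "heavy_intensity")]
  input <- tab[tab$sample == "input", c("prey", "peptide_seq", "light_intensity", "heavy_intensity")]
  idirt_experiment(bait, ip, if (nrow(input)) input else NULL)
}

#' Light fraction of one peptide pair, corrected for the input mixing ratio
#'
#' The raw light/heavy odds are divided by the normalizer (the input
#' sample's median odds, i.e. the realized mixing ratio) and converted back
#' to a fraction: `fraction = co / (1 + co)` with
#' `co = (L/H) / normalizer`. Zero heavy signal gives 1, zero light signal
#' gives 0, regardless of the normalizer.
#'
#' @param light,heavy channel intensities (not both zero)
#' @param normalizer positive mixing-ratio correction (1 = perfectly mixed)
#' @return fraction in [0, 1]
#' @export
peptide_light_fraction <- function(light, heavy, normalizer = 1) {
  stopifnot(normalizer > 0, light >= 0, heavy >= 0)
  if (light == 0 && heavy == 0) stop("both channel intensities are zero")
  if (heavy == 0) return(1)
  if (light == 0) return(0)
  co <- (light / heavy) / normalizer
  co / (1 + co)
}

#' Mixing-ratio normalizer from the input sample
#'
#' Median over quantifiable input proteins (those with at least two
#' peptides) of the per-protein median peptide light/heavy odds. For a
#' perfectly 1:1 mixed input this is 1.
#'
#' @param input_pairs input peptide data.frame (`prey`, `peptide_seq`,
#'   `light_intensity`, `heavy_intensity`), or `NULL`
#' @return positive normalizer; 1 (with a warning) when no input protein is
#'   quantifiable
#' @export
input_normalizer <- function(input_pairs) {
  if (is.null(input_pairs) || nrow(input_pairs) == 0L) {
    warning("no input sample; mixing-ratio normalization disabled (normalizer 1)")
    return(1)
  }
  # odds are undefined for single-channel peptides; exclude from the estimate
  q <- input_pairs[input_pairs$light_intensity > 0 & input_pairs$heavy_intensity > 0, ]
  per_protein <- vapply(split(q, q$prey), function(g) {
    if (nrow(g) < 2L) return(NA_real_)
    stats::median(g$light_intensity / g$heavy_intensity)
  }, numeric(1))
  per_protein <- per_protein[!is.na(per_protein)]
  if (length(per_protein) == 0L) {
    warning("no quantifiable input protein (>= 2 peptides); normalization disabled")
    return(1)
  }
  stats::median(per_protein)
}

#' Protein-level I-DIRT stability ratios
#'
#' Per prey with at least two quantified peptides, the stability ratio is
#' the median of the peptide light fractions (after mixing-ratio
#' correction). Preys with fewer than two peptides are dropped and reported
#' via the `dropped` attribute.
#'
#' @param exp an [idirt_experiment()]
#' @param normalizer mixing-ratio correction; defaults to
#'   [input_normalizer()] of the experiment's input sample
#' @return data.frame with columns `bait`, `prey`, `ratio`, `n_peptides`,
#'   `normalizer`; attribute `dropped` lists excluded preys
#' @export
protein_stability <- function(exp, normalizer = NULL) {
  if (is.null(normalizer)) normalizer <- input_normalizer(exp$input_pairs)
  p <- exp$pairs
  if (nrow(p) == 0L) {
    out <- data.frame(bait = character(), prey = character(), ratio = numeric(),
                      n_peptides = integer(), normalizer = numeric())
    attr(out, "dropped") <- character()
    return(out)
  }
  frac <- mapply(peptide_light_fraction, p$light_intensity, p$heavy_intensity,
                 MoreArgs = list(normalizer = normalizer))
  by_prey <- split(frac, p$prey)
  n_pep <- vapply(by_prey, length, integer(1))
  keep <- n_pep >= 2L
  out <- data.frame(
    bait = rep(exp$bait, sum(keep)),
    prey = names(by_prey)[keep],
    ratio = vapply(by_prey[keep], stats::median, numeric(1)),
    n_peptides = n_pep[keep],
    normalizer = normalizer,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "dropped") <- names(by_prey)[!keep]
  out
}
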