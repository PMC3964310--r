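CONTROL_BAIT <- "CONTROL"

#' Construct a spectral-count matrix
#'
#' A `count_matrix` holds non-negative integer spectral counts for a set of
#' prey proteins across a set of purification runs, together with prey
#' metadata (accession, protein length in amino acids) and run metadata
#' (bait gene or the `"CONTROL"` sentinel, replicate index). It is the input
#' container for specificity scoring, clustering and NSAF computation.
#'
#' Gene symbols (preys and baits) are stored uppercased so that reference
#' lists with mixed case match.
#'
#' @param counts integer matrix, preys in rows, runs in columns. Row names
#'   must be prey gene symbols and column names run ids.
#' @param preys data.frame with columns `gene`, `accession`, `length`
#'   (amino acids, >= 1), one row per row of `counts`.
#' @param runs data.frame with columns `run_id`, `bait` (gene symbol or
#'   `"CONTROL"`), `replicate_index` (positive integer), one row per column
#'   of `counts`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, preys, runs) {
  counts <- as.matrix(counts)
  preys <- as.data.frame(preys, stringsAsFactors = FALSE)
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  stopifnot(
    all(c("gene", "accession", "length") %in% names(preys)),
    all(c("run_id", "bait", "replicate_index") %in% names(runs)),
    nrow(counts) == nrow(preys),
    ncol(counts) == nrow(runs)
  )
  preys$gene <- toupper(preys$gene)
  runs$bait <- toupper(runs$bait)
  if (anyDuplicated(preys$gene)) {
    stop("duplicate prey gene symbols: ",
         paste(unique(preys$gene[duplicated(preys$gene)]), collapse = ", "))
  }
  if (anyDuplicated(runs$run_id)) {
    stop("duplicate run ids: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "))
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  bad_len <- is.na(preys$length) | preys$length < 1
  if (any(bad_len)) {
    warning("dropping ", sum(bad_len),
            " prey(s) with missing or invalid protein length (needed for NSAF): ",
            paste(preys$gene[bad_len], collapse = ", "))
    preys <- preys[!bad_len, , drop = FALSE]
    counts <- counts[!bad_len, , drop = FALSE]
  }
  if (any(runs$replicate_index < 1 | runs$replicate_index != round(runs$replicate_index))) {
    stop("replicate_index must be a positive integer")
  }
  storage.mode(counts) <- "double"
  rownames(counts) <- preys$gene
  colnames(counts) <- runs$run_id
  structure(list(counts = counts, preys = preys, runs = runs),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  nb <- sum(x$runs$bait != CONTROL_BAIT)
  nc <- sum(x$runs$bait == CONTROL_BAIT)
  cat(sprintf("count_matrix: %d preys x %d runs (%d bait, %d control)\n",
              nrow(x$counts), ncol(x$counts), nb, nc))
  cat("baits:", paste(unique(x$runs$bait[x$runs$bait != CONTROL_BAIT]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Runs belonging to a bait (or to the controls)
#' @param m a `count_matrix` or `normalized_counts`
#' @param bait bait gene symbol, or `"CONTROL"` for the control runs
#' @return character vector of run ids
#' @export
runs_for_bait <- function(m, bait) {
  m$runs$run_id[m$runs$bait == toupper(bait)]
}

#' Read a spectral-count matrix from a tab-delimited file
#'
#' Two dialects are supported. The *long* dialect has one row per observed
#' (prey, run) cell with columns `prey_gene`, `prey_accession`,
#' `prey_length`, `run_id`, `bait`, `count`; cells absent from the file read
#' as zero. The *wide* dialect has one row per prey (`prey_gene`,
#' `prey_accession`, `prey_length`, then one column per run) and declares
#' run metadata in `#run` comment lines of the form
#' `#run <run_id> <bait> <replicate_index>` preceding the header.
#' Lines starting with `#` are otherwise ignored; files are UTF-8.
#'
#' @param path file path
#' @param dialect `"long"` or `"wide"`
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "long") {
    read_count_matrix_long(lines, path)
  } else {
    read_count_matrix_wide(lines, path)
  }
}

read_count_matrix_long <- function(lines, path) {
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("malformed file (no data rows): ", path)
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  need <- c("prey_gene", "prey_accession", "prey_length", "run_id", "bait", "count")
  if (!all(need %in% names(tab))) {
    stop("malformed long-dialect header; need columns: ",
         paste(need, collapse = ", "))
  }
  if (any(is.na(tab$count)) || any(tab$count < 0) || any(tab$count != round(tab$count))) {
    stop("counts must be non-negative integers")
  }
  tab$prey_gene <- toupper(tab$prey_gene)
  tab$bait <- toupper(tab$bait)
  key <- paste(tab$prey_gene, tab$run_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (prey, run) cell(s): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  preys <- unique(tab[, c("prey_gene", "prey_accession", "prey_length")])
  names(preys) <- c("gene", "accession", "length")
  if (anyDuplicated(preys$gene)) {
    stop("prey metadata inconsistent across rows for: ",
         paste(unique(preys$gene[duplicated(preys$gene)]), collapse = ", "))
  }
  run_meta <- unique(tab[, c("run_id", "bait")])
  if (anyDuplicated(run_meta$run_id)) {
    stop("run assigned to more than one bait: ",
         paste(unique(run_meta$run_id[duplicated(run_meta$run_id)]), collapse = ", "))
  }
  run_meta <- run_meta[order(run_meta$bait != CONTROL_BAIT, run_meta$bait, run_meta$run_id), ]
  rep_idx <- stats::ave(seq_len(nrow(run_meta)), run_meta$bait, FUN = seq_along)
  runs <- data.frame(run_id = run_meta$run_id, bait = run_meta$bait,
                     replicate_index = rep_idx, stringsAsFactors = FALSE)
  counts <- matrix(0, nrow(preys), nrow(runs),
                   dimnames = list(preys$gene, runs$run_id))
  counts[cbind(match(tab$prey_gene, preys$gene), match(tab$run_id, runs$run_id))] <- tab$count
  count_matrix(counts, preys, runs)
}

read_count_matrix_wide <- function(lines, path) {
  run_lines <- lines[startsWith(lines, "#run")]
  if (length(run_lines) == 0L) {
    stop("malformed wide-dialect file: no '#run' metadata lines in ", path)
  }
  meta <- do.call(rbind, lapply(run_lines, function(l) {
    f <- strsplit(sub("^#run[ \t]+", "", l), "[ \t]+")[[1]]
    if (length(f) != 3L) stop("malformed '#run' line: ", l)
    f
  }))
  runs <- data.frame(run_id = meta[, 1], bait = toupper(meta[, 2]),
                     replicate_index = as.integer(meta[, 3]),
                     stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = body, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("prey_gene", "prey_accession", "prey_length")
  if (!all(need %in% names(tab))) {
    stop("malformed wide-dialect header; need columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(toupper(tab$prey_gene))) {
    stop("duplicated prey row(s): ",
         paste(unique(tab$prey_gene[duplicated(toupper(tab$prey_gene))]), collapse = ", "))
  }
  run_cols <- setdiff(names(tab), need)
  missing_meta <- setdiff(run_cols, runs$run_id)
  if (length(missing_meta)) {
    stop("run column(s) without '#run' metadata: ", paste(missing_meta, collapse = ", "))
  }
  runs <- runs[runs$run_id %in% run_cols, , drop = FALSE]
  counts <- as.matrix(tab[, runs$run_id, drop = FALSE])
  counts[is.na(counts)] <- 0
  preys <- data.frame(gene = tab$prey_gene, accession = tab$prey_accession,
                      length = tab$prey_length, stringsAsFactors = FALSE)
  count_matrix(counts, preys, runs)
}

#' Write a count matrix in the long dialect
#'
#' Emits the tab-delimited long dialect read by [read_count_matrix()]
#' (`prey_gene`, `prey_accession`, `prey_length`, `run_id`, `bait`,
#' `count`), one row per non-zero cell, so write-then-read is
#' cell-identical.
#'
#' @param m a [count_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(m, path) {
  idx <- which(m$counts != 0, arr.ind = TRUE)
  # ensure every run appears at least once so run metadata round-trips
  seen <- unique(colnames(m$counts)[idx[, 2]])
  unseen <- setdiff(m$runs$run_id, seen)
  if (length(unseen) && nrow(m$counts) > 0L) {
    idx <- rbind(idx, cbind(1L, match(unseen, colnames(m$counts))))
  }
  tab <- data.frame(
    prey_gene = m$preys$gene[idx[, 1]],
    prey_accession = m$preys$accession[idx[, 1]],
    prey_length = m$preys$length[idx[, 1]],
    run_id = m$runs$run_id[idx[, 2]],
    bait = m$runs$bait[idx[, 2]],
    count = m$counts[idx],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$prey_gene, tab$run_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove blocklisted preys (keratins, known contaminants)
#'
#' @param m a [count_matrix()]
#' @param blocklist character vector of gene symbols (case-insensitive); may
#'   be empty
#' @return the matrix without the blocklisted preys; counts unchanged
#' @export
clean_preys <- function(m, blocklist = character()) {
  keep <- !(m$preys$gene %in% toupper(blocklist))
  structure(list(counts = m$counts[keep, , drop = FALSE],
                 preys = m$preys[keep, , drop = FALSE],
                 runs = m$runs),
            class = class(m))
}

#' Zero the bait protein's own counts in its purifications
#'
#' In each bait run the spectral count of the bait's own gene product is set
#' to zero so the (inevitably huge) bait self-signal cannot distort
#' normalization, scoring or clustering. Control runs are untouched.
#'
#' @param m a [count_matrix()]
#' @param bait_prey_map named character vector mapping each bait name to the
#'   gene symbol of its product among the preys. Defaults to the identity
#'   (bait name == gene symbol).
#' @return the modified matrix
#' @export
zero_bait_self_counts <- function(m, bait_prey_map = NULL) {
  baits <- setdiff(unique(m$runs$bait), CONTROL_BAIT)
  if (is.null(bait_prey_map)) {
    bait_prey_map <- stats::setNames(baits, baits)
  } else {
    names(bait_prey_map) <- toupper(names(bait_prey_map))
    bait_prey_map <- toupper(bait_prey_map)
  }
  missing <- setdiff(baits, names(bait_prey_map))
  if (length(missing)) {
    stop("bait(s) missing from bait_prey_map: ", paste(missing, collapse = ", "))
  }
  counts <- m$counts
  for (b in baits) {
    g <- bait_prey_map[[b]]
    if (g %in% rownames(counts)) {
      counts[g, runs_for_bait(m, b)] <- 0
    }
  }
  structure(list(counts = counts, preys = m$preys, runs = m$runs),
            class = class(m))
}

#' Normalize a bait's spectral counts to the control background
#'
#' Counts in the bait's runs are multiplied by the ratio of the mean total
#' spectral count over control runs to the mean total over that bait's runs,
#' so the two groups have equal mean totals afterwards. Control runs (and
#' any other bait's runs) keep scale factor 1. Totals are computed on the
#' matrix as given, i.e. after any cleaning and bait self-count zeroing.
#'
#' @param m a [count_matrix()]
#' @param bait bait gene symbol
#' @return a `normalized_counts` object: same shape with real-valued counts
#'   and a `scale_factors` vector named by run id
#' @export
normalize_counts <- function(m, bait) {
  bait <- toupper(bait)
  ctrl <- runs_for_bait(m, CONTROL_BAIT)
  brs <- runs_for_bait(m, bait)
  if (length(ctrl) == 0L) stop("no control runs present")
  if (length(brs) == 0L) stop("no runs for bait ", bait)
  totals <- colSums(m$counts)
  bait_mean <- mean(totals[brs])
  if (bait_mean == 0) stop("degenerate input: bait ", bait, " has zero total counts")
  f <- mean(totals[ctrl]) / bait_mean
  sf <- stats::setNames(rep(1, ncol(m$counts)), colnames(m$counts))
  sf[brs] <- f
  counts <- sweep(m$counts, 2L, sf, `*`)
  structure(list(counts = counts, preys = m$preys, runs = m$runs,
                 scale_factors = sf, bait = bait),
            class = c("normalized_counts", "count_matrix"))
}
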