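# Small in-code fixtures shared across test files.

# 3 preys x (2 control + 2 bait) matrix with hand-chosen counts
tiny_matrix <- function() {
  counts <- rbind(
    PREYA = c(1, 3, 40, 38),
    PREYB = c(0, 0, 12, 10),
    BAITX = c(0, 1, 250, 260)
  )
  count_matrix(
    counts,
    preys = data.frame(gene = rownames(counts),
                       accession = paste0("ACC", 1:3),
                       length = c(400, 250, 500)),
    runs = data.frame(run_id = c("C1", "C2", "B1", "B2"),
                      bait = c("CONTROL", "CONTROL", "BAITX", "BAITX"),
                      replicate_index = c(1, 2, 1, 2))
  )
}

# long-dialect TSV text for the tiny matrix (written by tests that need a file)
write_tiny_long <- function(path, drop_cell = FALSE, dup_cell = FALSE) {
  m <- tiny_matrix()
  write_count_matrix(m, path)
  if (drop_cell) {
    l <- readLines(path)
    writeLines(l[-grep("^PREYA\tACC1\t400\tB1", l)], path)
  }
  if (dup_cell) {
    l <- readLines(path)
    writeLines(c(l, l[grep("^PREYA\tACC1\t400\tB1", l)[1]]), path)
  }
  path
}

# direct Bayes posterior from first principles (independent of dpois):
# Poisson mass as l^k * exp(-l) / k!, factorial as an explicit product
oracle_iprob <- function(k, lf, lt, pi) {
  mass <- function(k, l) l^k * exp(-l) / prod(seq_len(k))
  a <- pi * mass(k, lt)
  b <- (1 - pi) * mass(k, lf)
  a / (a + b)
}

# peptide-pair data.frame helper
pep <- function(prey, light, heavy, seq = NULL) {
  if (is.null(seq)) seq <- sprintf("%s_P%02d", prey, seq_along(light))
  data.frame(prey = prey, peptide_seq = seq,
             light_intensity = light, heavy_intensity = heavy,
             stringsAsFactors = FALSE)
}

# independent re-statement of the quadrant rules used as a cross-check below
truth_table_category <- function(s, r, pass = 0.75, stable = 0.80,
                                 cont_s = 0.10, cont_r = 1.0, tol = 1e-6) {
  s0 <- if (is.na(s)) 0 else s
  if (is.na(r)) {
    if (s0 >= pass) "unquantified" else "nonspecific"
  } else if (s0 < cont_s && r >= cont_r - tol) {
    "contaminant"
  } else if (s0 < pass && r >= stable) {
    "rescued"
  } else if (s0 >= pass && r >= stable) {
    "stable"
  } else if (s0 >= pass) {
    "dynamic"
  } else {
    "nonspecific"
  }
}

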