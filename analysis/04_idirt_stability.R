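#!/usr/bin/env Rscript
# Stage 4 — I-DIRT relative-stability ratios from SILAC peptide tables.
#
# Per bait: estimates the realized light:heavy mixing ratio from the input
# sample (median over input proteins of median peptide odds), corrects every
# peptide's light fraction, and reports per-protein medians (>= 2 peptides).
# Ratios near 0.5 indicate fast-exchanging interactions; 1.0 indicates
# stable, in-vivo specific (or light-only contaminant) proteins.

library(apmstability)

out <- "results"
pep_files <- list.files(out, pattern = "^peptides_.*\\.tsv$", full.names = TRUE)

stab <- do.call(rbind, lapply(pep_files, function(f) {
  b <- sub("^peptides_(.*)\\.tsv$", "\\1", basename(f))
  exp <- read_peptide_table(f, b)
  st <- protein_stability(exp)
  cat(sprintf("%s: %d proteins quantified (normalizer %.3f); ratios ~0.5: %d, = 1.0: %d\n",
              b, nrow(st), st$normalizer[1],
              sum(abs(st$ratio - 0.5) < 0.1), sum(st$ratio >= 1 - 1e-6)))
  st
}))
write.table(stab, file.path(out, "stability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
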