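#!/usr/bin/env Rscript
# Stage 5 — specificity x stability quadrant classification.
#
# Outer-joins the SAINT scores and I-DIRT ratios per (bait, prey) and
# classifies each profile: stable (pass + ratio >= 0.80), dynamic (pass +
# ratio < 0.80), rescued (below threshold but stable by I-DIRT), contaminant
# (score < 0.10 with maximal ratio), nonspecific, or unquantified (specific
# but undetected in I-DIRT).

library(apmstability)

out <- "results"
scored <- read.delim(file.path(out, "saint_results.tsv"))
stab <- read.delim(file.path(out, "stability.tsv"))
baits <- unique(scored$bait)

profiles <- do.call(rbind, lapply(baits, function(b) {
  classify_profiles(join_profiles(scored[scored$bait == b, ],
                                  stab[stab$bait == b, ]))
}))
write.table(profiles, file.path(out, "profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

qs <- quadrant_summary(profiles)
cat("quadrant counts over all baits:\n")
print(qs$counts)
cat(sprintf("%d of %d profiles are retained as interactions (contaminants and nonspecific excluded)\n",
            length(qs$interactions), qs$total))
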