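#!/usr/bin/env Rscript
# Control-region style motif survey over the synthetic profiles: pick
# the defining variants of the deepest labelled clade as a diagnostic
# motif, survey carrier frequencies per population, and roll the
# frequencies up by region — the table a spatial interpolation would
# consume.

library(mitofounder)

tree <- read_tree("results/synthetic/tree_rebuilt.nwk")
haps <- read_profiles("results/synthetic/profiles.tsv")

# diagnostic motif = the mutations on the branch of the first labelled
# subclade below the root
lab_nodes <- which(!is.na(tree$label) & tree$label != "SYN")
stopifnot(length(lab_nodes) > 0)
node <- lab_nodes[1]
motif <- haplogroup_motif(tree$label[node], tree$mutations[[node]],
                          parent = "SYN")
cat("Surveying motif", motif$label, "=",
    paste(motif$defining[[1]], collapse = " "), "\n")

freq <- motif_frequency(haps, motif)
utils::write.table(freq, "results/motif_frequencies.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(as.data.frame(freq), digits = 3)

roll <- regional_rollup(freq)
utils::write.table(roll, "results/motif_frequencies_by_region.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nRegional roll-up:\n")
print(as.data.frame(roll), digits = 3)
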