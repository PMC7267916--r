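#!/usr/bin/env Rscript
# Stage 3: random geodesic Voronoi parcellation.
#
# The cohort carries the parcellation its task maps were generated on; this
# stage summarizes it (coverage, connectivity, size balance) and exports
# the per-vertex label table.

library(taskpred)

cohort <- load_cohort("results/cohort")
parc <- cohort$truth$parcellation
print(parc)

sizes <- table(parc$labels[seq_len(cohort$space$n_cortical)])
cat(sprintf("cortical parcel sizes: min %d, median %d, max %d (max/min = %.1f)\n",
            min(sizes), median(sizes), max(sizes), max(sizes) / min(sizes)))
cat("all parcels connected:", taskpred:::parcels_connected(cohort$space, parc), "\n")

write.csv(parcel_table(parc), "results/parcellation.csv", row.names = FALSE)
cat("wrote results/parcellation.csv\n")
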