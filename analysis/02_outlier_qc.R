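#!/usr/bin/env Rscript
# Stage 2 — PCA-based outlier screening on the raw spectra.
#
# Mean-centered raw spectra are modelled with the fewest principal
# components explaining 90% of variance; each particle gets a reduced
# Hotelling T2 (distance within the score space) and a reduced Q residual
# (distance off the model plane), each divided by its 95% limit. A particle
# exceeding 1 on either statistic is excluded before preprocessing.

suppressPackageStartupMessages(library(evspec))

set <- read_spectra("results/spectra_raw.csv")
qc <- qc_spectra(set)
utils::write.csv(qc$report, "results/qc_report.csv", row.names = FALSE)
write_spectra(subset_spectra(set, !qc$report$flagged),
              "results/spectra_qc.csv")

cat(sprintf("PCA QC model: %d components\n", qc$n_components))
cat(sprintf("flagged %d of %d spectra (%.1f%%):\n",
            sum(qc$report$flagged), nrow(qc$report),
            100 * mean(qc$report$flagged)))
print(qc$report[qc$report$flagged, ], row.names = FALSE)
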