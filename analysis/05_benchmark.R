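#!/usr/bin/env Rscript
# Stage 5: benchmark against the truth manifest. The manifest's expected
# outcomes were computed from the planted parameters alone, so agreement
# here is a genuine end-to-end check of the whole screen.

library(ferromap)

out <- file.path("results", "benchmark")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

manifest <- read.delim(file.path("results", "community",
                                 "truth_manifest.tsv"))
meta <- read.delim(file.path("results", "community", "strain_meta.tsv"))
pm <- read.delim(file.path("results", "copynumber",
                           "presence_matrix.tsv"), check.names = FALSE)
mat <- as.matrix(pm[, -1]); rownames(mat) <- pm$strain_id
storage.mode(mat) <- "integer"
cls <- read.delim(file.path("results", "classify",
                            "classifications.tsv"))

tm <- truth_matrix(manifest, strains = meta$strain_id)
agree <- matrix_agreement(mat, tm[rownames(mat), colnames(mat)])

viol <- manifest[grepl("fragment|insertion", manifest$features), ]
viol_removed <- mean(!viol$contig_id %in% cls$contig_id)
tp <- manifest[grepl("transit_peptide", manifest$features) &
                 manifest$expected_survival, ]
tp_recall <- mean(tp$contig_id %in% cls$contig_id[cls$transit])
fu <- manifest[grepl("ubq_fusion", manifest$features) &
                 manifest$expected_survival, ]
fu_recall <- mean(fu$contig_id %in% cls$contig_id[cls$fusion])

summary <- data.frame(
  metric = c("presence_matrix_cell_agreement",
             "filter_violators_removed",
             "transit_peptide_recall",
             "ubq_fusion_recall"),
  value = c(agree, viol_removed, tp_recall, fu_recall),
  n = c(length(tm), nrow(viol), nrow(tp), nrow(fu)))
write.table(summary, file.path(out, "benchmark.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summary, row.names = FALSE)

bad <- which(mat != tm[rownames(mat), colnames(mat)], arr.ind = TRUE)
if (nrow(bad)) {
  cat("disagreeing cells:\n")
  for (i in seq_len(nrow(bad)))
    cat(sprintf("  %s / %s: pipeline %d vs truth %d\n",
                rownames(mat)[bad[i, 1]], colnames(mat)[bad[i, 2]],
                mat[bad[i, 1], bad[i, 2]],
                tm[rownames(mat)[bad[i, 1]], colnames(mat)[bad[i, 2]]]))
} else cat("pipeline matrix matches the truth manifest exactly\n")
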