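#!/usr/bin/env Rscript
# Stage 4: dereplication, trees and copy counts. Collapses maximal
# same-species clades on midpoint-rooted neighbor-joining trees (one per
# family) and emits the strain x family presence/copy matrix.

library(ferromap)

out <- file.path("results", "copynumber")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cls <- read.delim(file.path("results", "classify", "classifications.tsv"))
meta <- read.delim(file.path("results", "community", "strain_meta.tsv"))

cc <- count_family_copies(cls, meta)
mat <- presence_matrix(cc$records, strains = meta$strain_id)

write.table(cc$records, file.path(out, "copy_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(strain_id = rownames(mat), mat,
                       check.names = FALSE),
            file.path(out, "presence_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
tree_dir <- file.path(out, "trees")
dir.create(tree_dir, showWarnings = FALSE)
for (nm in names(cc$trees))
  ape::write.tree(cc$trees[[nm]], file.path(tree_dir, paste0(nm, ".nwk")))

cat("presence/copy matrix:\n")
print(mat)
cat(sprintf("trees written for %d families under %s\n",
            length(cc$trees), tree_dir))
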