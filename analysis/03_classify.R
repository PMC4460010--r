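#!/usr/bin/env Rscript
# Stage 3: functional classification. Evaluates the packaged motif and
# diagnostic-residue rules for every surviving candidate, resolves the
# Fe/Mn SOD metalloform and the flavodoxin clade, and calls plastid
# transit peptides (ferredoxin) and ubiquitin fusions (NiSOD).

library(ferromap)

comm_dir <- file.path("results", "community")
out <- file.path("results", "classify")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref_files <- list.files(file.path(comm_dir, "references"),
                        full.names = TRUE)
refs <- list()
for (f in ref_files) {
  fid <- toupper(sub("\\.fasta$", "", basename(f)))
  refs[[fid]] <- load_family(f, paste0(fid, "_ref1"), family_id = fid)
}
profiles <- list()
for (i in seq_along(refs))
  profiles[[names(refs)[i]]] <-
    calibrate_evd(build_profile(refs[[i]]), seed = 7L + i)

survivors <- read.delim(file.path("results", "screen", "survivors.tsv"))
cls <- classify_hits(survivors, refs, profiles)

write.table(cls, file.path(out, "classifications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("labels assigned:\n")
print(table(cls$label))
cat(sprintf("transit peptides called: %d; ubiquitin fusions called: %d\n",
            sum(cls$transit), sum(cls$fusion)))
if (any(cls$label == "rejected"))
  print(cls[cls$label == "rejected",
            c("hit_id", "family_id", "rejected_reason")])
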