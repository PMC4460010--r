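#!/usr/bin/env Rscript
# Stage 2: profile search and candidate-quality screen. Reads the
# community written by 01_simulate.R, rebuilds calibrated profiles from
# the reference FASTAs, six-frame translates every strain, retrieves
# candidates at e-value 1e-05 and applies the span (25-500%), insertion
# (>50 aa) and within-strain duplicate filters.

library(ferromap)

comm_dir <- file.path("results", "community")
out <- file.path("results", "screen")
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

meta <- read.delim(file.path(comm_dir, "strain_meta.tsv"))
all_hits <- list(); reports <- list()
for (s in meta$strain_id) {
  contigs <- read_fasta(file.path(comm_dir, paste0(s, ".fasta")), "DNA")
  peps <- translate_contigs(contigs, s, min_orf_aa = 30L)
  hits <- search(profiles[names(profiles) != "UBQ"], peps)
  reports[[s]] <- apply_screen_filters(hits, refs)
  all_hits[[s]] <- hits
  cat(sprintf("%s: %d ORFs, %d hits, %d survive the screen\n",
              s, nrow(peps), nrow(hits),
              reports[[s]]$counts[["survivors"]]))
}

hits <- do.call(rbind, c(all_hits, list(make.row.names = FALSE)))
survivors <- do.call(rbind, c(lapply(reports, `[[`, "survivors"),
                              list(make.row.names = FALSE)))
counts <- do.call(rbind, lapply(names(reports), function(s)
  data.frame(strain_id = s, t(reports[[s]]$counts))))

write.table(hits, file.path(out, "hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(survivors, file.path(out, "survivors.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(counts, file.path(out, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("total: %d hits, %d survivors (removed: %d short, %d long, %d insertion, %d duplicate)\n",
            nrow(hits), nrow(survivors), sum(counts$removed_short),
            sum(counts$removed_long), sum(counts$removed_insertion),
            sum(counts$removed_duplicate)))
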