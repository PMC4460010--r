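#!/usr/bin/env Rscript
# Stage 1: build the default synthetic community -- 12 strains, the 12
# screened iron-metabolism gene families, planted homologs with protected
# functional sites, filter violators, transit-peptide and fusion
# architectures, and shuffled decoys -- plus the truth manifest.

library(ferromap)

out <- file.path("results", "community")
comm <- build_community(community_spec(), out_dir = out)

m <- comm$manifest
cat("community written to", out, "\n")
cat(sprintf("  strains: %d, contigs: %d (plantings %d, decoys %d)\n",
            length(comm$strain_fastas), nrow(m),
            sum(m$features != "decoy"), sum(m$features == "decoy")))
cat(sprintf("  filter violators planted: %d (fragments %d, insertions %d)\n",
            sum(grepl("fragment|insertion", m$features)),
            sum(grepl("fragment", m$features)),
            sum(grepl("insertion", m$features))))
cat(sprintf("  transit peptides: %d, ubiquitin fusions: %d\n",
            sum(grepl("transit_peptide", m$features)),
            sum(grepl("ubq_fusion", m$features))))
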