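---
title: "Profile-based screening of iron-metabolism gene families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based screening of iron-metabolism gene families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferromap)
```

# The problem

Diatoms and other marine microeukaryotes manage iron with a recurring panel
of gene families: the reductive uptake system (ferric reductase FRE,
multicopper oxidase MCO, iron(III) permease FTR), iron storage (ferritin
FTN), iron-sparing electron carriers (flavodoxin FLDA replacing ferredoxin
PETF; plastocyanin PCYN replacing cytochrome c6 CYTC6), and the four
superoxide dismutase metalloforms (Fe, Mn, Cu-Zn and Ni). Surveying these
families across hundreds of transcriptome assemblies requires a screen that
is tolerant of fragmentary contigs and deep sequence divergence, yet strict
about the biochemical features that define each family. `ferromap`
implements that screen as a reproducible pipeline:

1. six-frame translation of contigs into stop-to-stop open reading frames;
2. retrieval by position-specific scoring models built from reference
   peptides, with extreme-value calibrated e-values (cutoff 1e-05);
3. quality filters: span (25%-500% of the mature reference), unique
   internal insertions (over 50 aa removed), within-strain 100%-identity
   duplicates;
4. functional classification by degenerate motifs and diagnostic residues;
5. detection of two architectures: plastid transit peptides on ferredoxin
   and ubiquitin-NiSOD fusion genes;
6. per-strain paralog copy counting by collapsing same-species clades on
   midpoint-rooted neighbor-joining trees, after dereplication at >95%
   identity.

Every stage is also exercised by a synthetic-community generator with a
complete truth manifest, so the whole pipeline is testable without any
external download.

# The profile model

The retrieval step is a self-contained profile model rather than a wrapper
around an external search binary, so the package has no runtime
dependencies beyond R. Each reference family is star-aligned to its
designated anchor sequence and trimmed to the mature protein region; one
match state is created per anchor column.

**Emissions.** Match-state emissions are Dirichlet-style smoothed log-odds
in bits,

$$ e_k(a) = \log_2 \frac{(c_{k,a} + w\,p_a) / (n_k + w)}{p_a}, $$

where $c_{k,a}$ counts residue $a$ in column $k$, $n_k$ is the number of
observed residues, $p_a$ the background frequency (a packaged
Robinson-Robinson-style table) and $w$ the pseudocount weight (default 1).
A column that equals the background scores exactly zero bits. The unknown
residue X scores the background expectation $\sum_a p_a e_k(a)$ of its
column.

**Transitions.** Match/insert/delete transition probabilities are
estimated per inter-state boundary from the alignment's gap and insertion
structure with Laplace-style pseudocounts (prior M->M/I/D = 0.9/0.05/0.05,
strength 1), normalized per source state before the log transform.

**Scoring.** Local alignment allows free entry into and exit from any
match state; insert states emit at background (zero bits). Viterbi (best
path) and forward (log-sum over all local paths) are computed in a single
dynamic-programming pass in C++. Forward is always at least Viterbi; the
test suite verifies both scores against exhaustive path enumeration on
tiny profiles.

**E-values.** Each profile is calibrated by scoring `null_count = 200`
background sequences of length 400 and fitting a Gumbel distribution by
maximum likelihood (Newton iterations on the scale parameter, tolerance
1e-9; location from the profile likelihood). Then

$$ E(s) = N \left(1 - \exp(-e^{-\lambda (s - \mu)})\right), $$

with $N$ the number of peptides searched in the strain (per-strain
normalization: the screen operates per transcriptome). The calibration is
seeded and bit-reproducible. The two-parameter Gumbel is an approximation
to the true null maximum distribution; it is accurate enough that planted
homologs at 55% identity score 30+ orders of magnitude below the cutoff
while shuffled decoys essentially never pass, and the fitted CDF renders
the calibration sample uniform (Kolmogorov-Smirnov consistency is part of
the acceptance checks). E-values of real hits are therefore indicative
rather than exact tail probabilities — the screen uses them only as a
threshold at 1e-05, far from the fitted region's edge.

# Anchors, rules and coordinates

All residue-level rules are expressed in 1-based positions on a family's
anchor sequence (e.g. "Cys37" on the ferredoxin anchor). A candidate is
mapped onto anchor coordinates by global Needleman-Wunsch alignment with
BLOSUM62, gap open 11, gap extend 1 (via `Biostrings::pairwiseAlignment`).
This pairwise anchoring replaces inspection of a multiple alignment: it is
deterministic, testable, and independent of which other candidates are in
the batch.

The packaged rule sets:

| Family | Gate | Source of coordinates |
|---|---|---|
| FRE | FAD motif `H-P-F-[ST]-[VLI]` and NADPH motif `C-[GAV]-P` | motif only |
| MCO | all four Cu-binding regions (Fet3p numbering: 78-85, 121-128, 413-420, 478-489), His/Cys ligands required | yeast Fet3p |
| FTR | at least two `R-E-X-X-E` motifs | motif only |
| FTN | ferroxidase-center residues; 130/131 as an either/or pair; iron-release sites report-only | PmFTN numbering |
| PETF | Cys at 37, 42, 45, 75 | ferredoxin anchor |
| PCYN | His37 and Cys84 required; His87/Met92 report-only | plastocyanin anchor |
| FESOD/MNSOD | site 77 (Q vs G) and site 146 (A/G vs Q) decide the metalloform | SOD numbering |
| CUZNSOD | ligands 46, 48, 63, 71, 80, 120, 83 all report-only; graded full/partial | spinach numbering |
| NISOD | N-terminal Ni-hook `H-C-X-X-P-C-G-X-Y` within 40 residues | motif only |
| CYTC6, FLDA | no residue gate | — |

Three deliberately open choices, decided as follows:

* **Fe/Mn SOD sites are not gates.** A candidate retrieved by the Fe
  profile whose sites read G77/Q146 is relabelled MnSOD by
  `classify_sod()` rather than rejected; combinations outside the
  two-row decision table are reported as "ambiguous" and retained,
  because the screen's manual antecedent had no stated discard rule.
* **MCO ferroxidase residues (185, 283, 409) are report-only**: the acidic
  residues implicated in yeast ferroxidase specificity are not conserved
  in diatoms, so requiring them would reject genuine diatom MCOs.
* **PCYN's two unnamed Cu ligands** ship as annotation-derived defaults
  (His87, Met92 in plastocyanin numbering), report-only and flagged as
  unverified; only His37 and Cys84 gate the call.
* **FTN ferroxidase-center positions** other than the 130/131 either/or
  pair (17, 50, 53, 94 in the packaged anchor) are annotation-derived
  defaults and configurable.

Report-only rules can never change a label; the suite verifies this by
exhaustively mutating report-only sites.

# Architectures

**Plastid transit peptides.** Diatom plastid-targeted ferredoxins carry a
conserved motif at the signal/transit-peptide junction, with cleavage
between an A/G and the following F. The detector requires (a) at least
`min_extension = 15` residues upstream of where the mature anchor's first
column maps (real leaders are ~20+ residues; 15 is conservative), and (b)
the degenerate pattern `[AG]-F-[AVMLI]-P` straddling the junction, its A/G
inside the leader. The set of accepted variants is expressed entirely in
that one configurable pattern, and each call records the matched variant.
The mature chain starts at the F.

**Ubiquitin-NiSOD fusions.** Most diatom NiSOD transcripts encode
ubiquitin immediately upstream of the Ni-hook. A fusion is called iff the
region upstream of the hook scores against the ubiquitin profile at the
acceptance e-value and ends in a diglycine within 5 residues of the hook
region, reflecting processing by ubiquitin-specific proteases, which
cleave after the ubiquitin-terminal GG. After a positive call the Ni-hook
window is re-anchored at the cleavage site, and tree building uses the
cleaved mature chain (fused candidates would otherwise cluster by their
identical ubiquitin moiety).

# Filters and their boundary semantics

Thresholds are taken literally from their verbal definitions: spans of
exactly 25% or 500% survive ("less than"/"greater than" remove), a
50-residue insertion survives ("over 50" removes), only 100% identity
deduplicates, and dereplication merges strictly above 95%. Span is
candidate ungapped length over mature reference length; the alternative
(aligned anchor coverage) is deliberately not the default because
fragmentary ORFs with leaders or fusions would be penalized twice. The
insertion run is measured against the family member the candidate aligns
to best — measuring against a single distant anchor blurs insertions in
divergent paralogs (this mattered in practice for clade-II flavodoxins
judged against a clade-I anchor). Filters apply in the fixed order span ->
insertion -> duplicate so every removal has exactly one recorded cause,
and each filter is idempotent.

# Copy counting

Presence and copy number are read off a per-family tree: sequences are
dereplicated at >95% identity (single linkage; representative = longest
member), pairwise identities are transformed to distances
$d = -\ln(\max(\mathrm{id}, 0.01))$ (Poisson-style, floored so unrelated
pairs stay finite), a neighbor-joining tree is built and midpoint-rooted,
and every maximal clade whose tips all share one species is collapsed into
a single node. A strain's copy number for a family is the number of
collapsed nodes containing at least one of its sequences — dereplicated
cluster members included, so a strain folded into another strain's
representative still counts. "Maximal same-species clade" is the
deterministic formalization of counting independently clustering paralogs
while treating same-species neighbors as alleles or assembly artifacts; no
attempt is made to distinguish the two. With fewer than three sequences no
tree is built: two same-species sequences collapse, anything else stands
alone.

`ape::nj()` and `phangorn::midpoint()` provide the tree machinery;
the clade collapse and its brute-force enumeration oracle are implemented
independently of each other.

# The synthetic community

`make_reference_families()` builds miniature reference families
(~90-500 aa) whose anchors embed the packaged rules at exactly the anchor
coordinates the rules test — cysteines at 37/42/45/75 for ferredoxin,
sites 77/146 for the Fe/Mn SODs, the four Fet3p-numbered Cu regions for
MCO (whose anchor is 500 aa so that region IV can sit at 478-489; honoring
the published coordinates took precedence over keeping every family under
450 aa). The ubiquitin family uses the canonical 76-residue sequence.

`build_community()` plants, per strain and family, homologs derived in two
steps: an ortholog-group ancestor at 68-80% identity to the reference
(shared by all strains, one per gene copy) and a strain copy at 90-96%
identity to its ancestor. This gives final identities of roughly 55-95%
versus the reference, keeps same-group cross-strain identities (~85%)
safely below the 95% dereplication threshold, and keeps cross-group
identities (~50%) far below same-group ones, so trees cluster by ortholog
group and copy counts are well defined. Substitutions are drawn from a
similarity-biased table (BLOSUM62 rows renormalized over non-identical
residues) at uniformly chosen unprotected positions; all rule sites are
protected. The default study condition is 12 strains (two being
subspecies of one species, to exercise the clade collapse), the copy
structure FRE x2, MnSOD x2 and one copy of everything else, 8% fragment
and 8% long-insertion violators, transit peptides on 75% of ferredoxin
plantings, fusions on 75% of NiSOD plantings, and 15 shuffled decoys per
strain — rates chosen to exercise every rule at desk scale while leaving
most plantings clean.

The truth manifest's `expected_survival` and `expected_label` are computed
from the planted parameters and declared thresholds alone, never by
running the pipeline, so pipeline-versus-manifest agreement is a genuine
test. What the generator does *not* emulate — sequencing error,
alternative splicing, compositional bias, genuinely novel domain
architectures, real phylogenetic rate variation — bounds what a passing
benchmark shows: the pipeline correctly executes its stated rules on data
matching its assumptions; it does not validate the rules against real
transcriptomes.

# Numerical choices and degenerate inputs

* Gumbel fit: Newton iterations, tolerance 1e-9, halving steps if the
  scale would go non-positive; degenerate score variance (< 1e-12) is a
  fatal calibration error.
* Alignment ties are resolved by `Biostrings::pairwiseAlignment`'s
  deterministic traceback; scores are symmetric.
* Neighbor joining ties are resolved by `ape::nj`'s deterministic
  implementation; negative NJ branch lengths are clamped to zero before
  midpoint rooting.
* ORF policy: stop-to-stop segments, leading Met not required, minimum
  30 aa — assembled contigs are fragments, so requiring ATG would drop
  real hits. Codons containing N translate to X; X matches only wildcard
  motif positions and scores the background expectation in profiles.
* Empty strain inputs yield an all-zero matrix row, not an error.
* Every stage's RNG is seeded (calibration per profile, community by
  spec); identical configuration reproduces byte-identical outputs.

# Problem sizes

The suite and the acceptance script run the full pipeline on the default
12-strain community (~360 contigs, ~1,200 ORFs against 13 profiles), check
the motif engine against a regex oracle on 10,000 peptides per rule, the
clade collapse against brute-force enumeration on 1,000 random trees of up
to 30 tips, neighbor joining on 200 additive matrices of 5-12 taxa, and
forward/Viterbi dominance on 1,000 random pairs. These sizes were chosen
so each check has enough cases to be meaningful while the whole suite
completes in minutes on one core.

# Known limitations

* The profile model is intentionally compact: no per-position insert
  emissions, no glocal mode, no heuristic acceleration. It is sized for
  desk-scale screens, not for genome-wide scans.
* E-values inherit the Gumbel approximation; comparisons across profiles
  of very different lengths are approximate.
* The insertion filter sees only the best-matching reference; a candidate
  whose closest reference is itself unusual may be misjudged. More
  generally, alignment-based insertion measurement has slack of roughly
  ten residues on short, divergent references: a random insertion can be
  partially absorbed as spurious matches, so an insertion marginally over
  the 50-residue limit occasionally measures at or below it.
* Copy counting depends on tree topology only through the collapse rule;
  very short internal branches can flip a same-species pair in or out of
  a clade, which is exactly the ambiguity the rule is meant to absorb.
* External maximum-likelihood trees can be supplied to the copy-counting
  stage (`ape::read.tree` objects are accepted directly), but the package
  never infers ML trees itself.
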