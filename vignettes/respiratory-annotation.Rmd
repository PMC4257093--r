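---
title: "Annotating respiratory capacity in gut microbial genome panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating respiratory capacity in gut microbial genome panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutresp)
```

`gutresp` turns a panel of finished and draft bacterial genomes into
predictions of respiratory phenotype: which terminal reductases each
genome encodes, how the organism relates to oxygen, and which nitrogen-
oxide intermediates it could trade with its neighbours. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, and what the package's synthetic test panels do and do
not demonstrate about real data.

## The annotation model

### Genome completeness

Draft genomes confound absence of a gene with absence of the contig that
carries it. The package therefore assesses draft completeness before any
phenotype call, by length comparison: a draft is *probably complete* when
its length is at least that of one closely related finished genome, where
relatedness is resolved in tiers — same species, else same genus, else the
finished genome(s) of maximal 16S identity, with all ties included to keep
the comparison set conservative. "At least" is deliberate: a draft exactly
as long as a finished relative shows no evidence of truncation, so ties
count as complete. Drafts with no related finished genome are
*unassessable* and are treated like incomplete genomes downstream.

An essential-gene fraction (`essential_gene_fraction()`) is computed as a
diagnostic only. It cannot support a verdict threshold: a perfectly
finished genome can score as low as ~0.85 on a generic essential-family
list, so any cutoff that keeps such genomes also keeps badly truncated
drafts.

### Reductase calling by orthology with genomic context

Function transfer by raw similarity is the classic source of reductase
misannotation, because catalytic subunits of different substrate
specificity can be close homologs. Calls are therefore based on **best
bidirectional hits** (BBH) to curated reference proteins, with two guards:

* both directed e-values must pass `ortholog_evalue_cutoff` (default
  1e-20; the family-level searches that only enumerate candidate members
  use 1e-10 and never drive presence calls);
* the pair must be **context-confirmed**: at least one other BBH pair must
  link genes within `window_k` genes (default 5) of both members. Operonic
  neighbourhoods are the stable unit of bacterial gene order, and five
  genes covers typical reductase operons with a margin; the window is a
  package choice, exposed as a parameter, and `call_reductases()` can
  relax the requirement (`require_context = FALSE`).

Ties in best-hit selection break by higher bitscore, then lexicographic
subject id, so results are invariant to input row order. Presence of a
reductase requires a catalytic-subunit ortholog only — membrane anchors,
electron-transfer subunits and maturation factors vary combinatorially
between genomes (the "Lego" principle) and are recorded for the audit
rather than required. Copy number counts distinct catalytic orthologs.

The reductase catalog is an editable YAML seeded with the types named in
the package's domain (aerobic Cyo/Qox/Cta/Cco; microaerobic Cyd/Cyf;
anaerobic Frd, Nar, Nap, Nrf, NirK, Nor, Nos, Dms, Tor, Ttr, Phs, Tsr,
Ynf, Asr, Apr, Hdr, Arr; assimilatory NirBD/NasBA and the NarK antiporter
with category `none`). A NirK (copper nitrite reductase) entry fills the
NO2→NO step, without which no catalog could express a complete
denitrification route. Hydrogenase-like entries can be added but carry no
oxygen category and never affect classification.

### Substrate specificity in the molybdopterin oxidoreductase family

Many anaerobic reductases share a catalytic-subunit family (PF00384) whose
members decide substrate specificity. Two assignment routes run in order:

1. **Clade propagation** (`propagate_by_clade()`): a maximal clade whose
   experimentally known tips agree on one specificity, and whose tips'
   genomic-context signatures pairwise share at least one neighbour
   family, passes that specificity to its unknown tips. "Pairwise share at
   least one accession" is the package's quantification of "conserved
   context within a branch"; no established number exists. Known labels
   are never overwritten; clades mixing specificities propagate nothing.
   Unrooted trees are midpoint-rooted by default (`unrooted = "error"`
   rejects instead) — rooting is not part of the input contract, and
   midpoint rooting is the standard neutral choice.
2. **SDP classification** (`fit_sdp()`, `classify_by_sdp()`): for members
   the tree cannot place, alignment columns are ranked by mutual
   information between residue and known-group label, computed over
   non-gap entries. A column is excluded outright when any group exceeds
   `sdp_max_gap_fraction = 0.5` gaps in it; surviving columns are kept at
   a z-score ≥ 3 against a label-permutation null (200 permutations by
   default). Classification sums per-group log-frequencies
   (Laplace-smoothed, pseudocount 0.5) over the selected columns and
   assigns the top group only when its margin over the runner-up reaches
   `margin = 2` natural-log units; anything less, or a protein gapped at
   every selected column, stays unknown. The margin trades coverage for
   precision; 2 log-units corresponds to a ~7-fold likelihood ratio.

Members neither route reaches stay `unassigned` — no guessing.

### Screening for novel reductases

Three screens look beyond the catalog:

* the **candidate cascade** (`run_cascade()`): keyword-matched domain
  families → signal peptide and/or ≥1 transmembrane segment → operon
  containing a partner from a configurable family set (default AhpC/TSA,
  the oxygen/thiol-binding family). Each stage is a subset of the last and
  the full trace is returned.
* the **co-occurrence filter** (`cooccurrence_filter()`): a candidate
  operon survives only with an ortholog-complete counterpart operon in
  every strain of a panel; an empty panel keeps everything (the universal
  quantifier is vacuous).
* the **orphan-accessory scan** (`orphan_accessory_scan()`): operons with
  ≥2 distinct accessory-subunit families of one catalog entry, no
  catalytic subunit of that entry, and ≥1 member of an alternative
  catalytic family (default: c-552/4-like cytochromes). One accessory
  homolog is too weak to imply a complex, hence the threshold of 2.

Operons themselves are structural proxies: maximal runs of same-strand,
same-contig genes with intergenic gaps ≤ `operon_max_gap_bp = 300` bp, a
conventional bacterial operon gap. The 187-family keyword list is a user
input; the package does not query domain databases.

### Oxygen lifestyle and consistency scoring

For complete and probably complete genomes the rule is a strict cascade:
any aerobic-category reductase ⇒ *aerophilic*; else any microaerobic
reductase ⇒ *microaerophilic* (a **strong microaerobe** when no anaerobic
reductase is present either); else *anaerobic*. Incomplete genomes can
only be bounded: an aerobic oxidase still proves aerophily, a microaerobic
oxidase proves *at least microaerophilic*, and an empty complement only
supports *most likely anaerobic*. Classification refuses genomes with
unassessed completeness.

External labels are reconciled through a shipped mapping table
(aerophilic ↔ aerobe/facultative; the microaerophilic classes ↔
microaerophile/facultative/nanaerobe; the anaerobic classes ↔
anaerobe/obligate anaerobe). Labels in the vocabulary but mapped to no
class (e.g. "aerotolerant") count as inconsistent with a warning; labels
outside the vocabulary are rejected rows, reported separately. Genomes are
partitioned by label availability (both sources / metadata only /
assertion only / none) and consistency is reported per group and pooled
over all metadata-bearing genomes.

### Pathway profiles and exchange networks

Pathway profiles map called enzymes onto five steps (NO3→NO2, NO2→NH3,
NO2→NO, NO→N2O, N2O→N2) with respiratory/assimilatory mode tags.
Ammonification is complete with NO3→NO2 + NO2→NH3; denitrification with
the four-step chain to N2. Only respiratory enzymes complete a route by
default — assimilatory nitrate/nitrite reduction is biosynthesis, not
energy conservation.

An exchange edge (producer, metabolite, consumer) for nitrite or nitric
oxide requires: the producer respires the producing step and has **no**
enzyme, respiratory or assimilatory, for the consuming steps (it must
actually excrete the intermediate); the consumer respires a consuming step
and lacks the producing step; and both genomes are co-habitation eligible.
Assimilatory enzymes thus block self-sufficiency but never create
producers. The default eligibility — both partners microaerobic-capable or
both anaerobic-class — encodes the observation that exchange partners must
share a zone of the gut's oxygen gradient; it is configurable. Producer
status requires only the immediately upstream step, not a full route from
nitrate. Nitrous-oxide edges exist behind `include_n2o = FALSE` because a
single-denitrifier community makes them speculative.

### The composition audit

`audit_complex()` reports matched subunit roles per called instance,
predicts complex localization from member features (any TM segment ⇒
membrane; else any signal peptide ⇒ extracellular; else cytoplasmic), and
flags **soluble variants**: catalytic subunit present, every membrane-
anchor role of an anchor-bearing entry absent. Because anchors can be
encoded far from the catalytic gene, a genome-wide search for unlinked
anchor homologs downgrades the flag to *distally encoded* before anyone
reads it as a missing component. Duplicated catalytic subunits where one
copy audits membrane-associated and another cytoplasmic are reported as
candidate assimilatory duplicates. Whether soluble variants really are
assimilatory is left open, as it is in the field; the audit annotates and
never alters presence calls.

## What the synthetic panels emulate

`generate_panel()` builds a deterministic panel from counts, not
probabilities, so realized marginals equal planted marginals exactly and
regression tests can be exact. The default specification encodes the study
conditions used throughout the tests: 254 genomes — 55 finished, 149
probably complete, 50 incomplete; oxygen classes 25/92/87 among the 204
complete genomes (27 strong microaerobes, one aerophile without
microaerobic backup) and 4/19/27 among the incomplete; a nitrogen-oxide
pathway mix of 28 complete ammonifiers, 1 complete denitrifier and 44
partial-pathway genomes (8 nitrate-only, 29 nitrite-to-ammonia-only, 1
nitrate-to-NO, 3 nitrate-plus-NO-to-N2O, 3 NO-to-N2O-only); label
availability 98/136/5/15 with 56 and 122 consistent metadata rows; a
candidate cascade of 75 → 7 → 3 over 187 keyword families on a host genome
whose 5-strain species panel shares two of the three context operons; one
orphan accessory operon; a 12-copy amplified reductase genome and the
soluble/extracellular/duplicated-copy audit fixtures. Similarity tables
plant ortholog bitscores (≥450) strictly above off-target decoys (350),
with e-values a fixed monotone function of bitscore.

Genome lengths, gene layout and taxon labels exist only to make the
completeness tiers and operon logic exercise correctly; they are not
realistic genome models. The panels contain no sequences, no alignment
errors, no annotation noise, no horizontal transfer, and their similarity
structure is planted rather than computed from evolution. Green tests
therefore demonstrate that the *algorithms* implement their definitions
and recover planted truth — not that the biological error rates on real
genomes are small. On real data, accuracy is bounded by the curation of
the reference catalog and by BLAST/localization/tree inputs produced
upstream of this package.

`generate_family_fixture()` plants monophyletic specificity clades (100
tips, 8 groups and 25% known tips by default), context signatures
conserved within clades, 16 SDP columns at 5% emission noise, and 12
members detached into a mixed clade that only the SDP route can recover.
Over 20 seeds the two-stage assignment recovers ≥95% of planted labels;
with zero noise, recovery is exact. Test problem sizes (a 20-genome panel
for oracle-equivalence suites, 30–60-tip trees for invariant suites, the
254-genome panel for the acceptance script) were chosen so the whole suite
exercises every path at interactive speed.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive (GFF convention) everywhere; nothing
  converts.
* Reported percentages use round-half-up at the requested precision
  (default one decimal). Half-up at one decimal can move each summand of a
  partition by just under 0.05, so a k-part partition is conserved within
  0.05·k; the 2–3-way partitions the reports actually print stay within
  ±0.1. Published tables rounded by other conventions (including
  truncation) can differ in the last digit — e.g. 132/254 is 52.0% here,
  not 51.9% — and such discrepancies are documented rather than imitated.
* Score ties in best-hit selection and SDP group ordering break
  deterministically (bitscore, then lexicographic id; ties below the SDP
  margin return unknown).
* Degenerate inputs fail loudly or vacuously by design: empty essential-
  family sets and unset completeness are errors; an empty keyword set
  yields an empty cascade; an empty strain panel keeps all operons; an
  empty catalog entry list, a missing catalytic subunit, or an unknown
  category reject the catalog; SDP models where every column is
  gap-filtered are flagged `empty` and classify nothing.

## Known limitations

* Calls inherit every upstream error: localization features, similarity
  scores and trees are inputs, not computed here.
* The catalog is deliberately minimal; absence of an exotic reductase
  family from it reads as absence from the genome.
* Exchange inference is qualitative — a directed possibility graph, not a
  flux model; co-habitation eligibility is a coarse proxy for spatial
  overlap in the gut.
* The essential-gene diagnostic and the length-based completeness verdict
  both depend on the finished relatives available; a genus with no
  finished genome leaves drafts unassessable.
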