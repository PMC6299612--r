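---
title: "Signature-based discovery and gain/loss analysis of GDPD-like SMase D/PLD families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based discovery and gain/loss analysis of GDPD-like SMase D/PLD families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldfam)
```

## The scientific problem

Sphingomyelinase D / phospholipase D (SMase D/PLD) toxins — best known from
sicariid spider venoms and a handful of pathogenic bacteria and fungi —
form a protein domain family derived from the ubiquitous
glycerophosphoryl diester phosphodiesterases (GDPDs). The family falls
into three major clades: a sicariid-toxin-like (ST-like) clade rooted in
chelicerates, an actinobacterial-toxin-like (AT-like) clade of bacterial
and fungal homologs, and an "Aquatic" clade scattered across marine and
freshwater metazoans and a few single-celled eukaryotes, plus a basal,
largely proteobacterial group. Their taxonomic distribution is strikingly
patchy: entire phyla that are well represented in sequence databases lack
any detectable homolog. `pldfam` implements the desk-scale analytical
machinery for studying this family: screening of similarity-search output,
sequence curation, signature-based clade classification, and
reconciliation of the family's presence/absence pattern with the
organismal tree under explicit gene gain/loss models.

## Diagnostic sequence signatures

Family membership and clade assignment rest on features that can be read
off a sequence-to-profile alignment:

* **C-terminal plug motif** — a ~17-column stabilising motif (an Arg-Asp
  salt bridge, hydrophobic Ala and Pro, and a buried Trp) shared by every
  family member and absent from GDPDs; a synapomorphy of the family.
* **βα1 loop length** — short (≤ 3 residues by default) in the family; at
  least six residues longer in true GDPDs, which carry a GDPD-insert
  domain that the family has lost.
* **Catalytic (βα2) loop** — the clade fingerprint. ST-like: conserved
  15-residue loop with a disulfide-bonded cysteine pair plus a third
  cysteine linking to the βα6 loop. AT-like: shorter (9–13 residues),
  variable, cysteine-free. Aquatic: ≥ 17 residues, retaining the ST pair
  plus at least one additional pair. Basal sequences have a short,
  cysteine-free loop, which is why the loop signature cannot separate
  AT-like from basal members — the classifier reports that ambiguity in
  its rule trace rather than hiding it.
* **Active site** — His12, Glu32, Asp34, His47, Asp91, Lys93 in mature
  numbering (profile column labels, not raw record positions).
* **DUF-B repeats** — a ~70-residue cysteine-rich repeat (ten conserved
  cysteines, a glycine-rich stretch, a terminal tyrosine) carried in 1–4
  copies by most Aquatic members.

The classifier applies these in a fixed decision order: non-family (no
plug, or GDPD-length βα1 loop, or unmappable), then ST-like, Aquatic,
AT-like, and finally basal/unclassified. Every call carries a rule trace
listing the comparisons made.

### The reference profile

No machine-readable alignment of real family exemplars is packaged, so the
reference profile is built from synthetic exemplars that encode the
signatures above (`build_reference_profile()`); a user alignment can be
substituted via its `alignment` argument. Columns are scored as log-odds
of per-column residue frequencies (Laplace pseudocount 1) against a
uniform background. The log-odds are expressed in half-bit units — the
BLOSUM convention — so that the affine gap penalties (open 10, extend 1)
act on their usual scale; with natural bits the penalties overwhelm the
column signal and alignments of loop-length variants slip out of register.
Records are aligned to the profile by an ends-free global dynamic
programme (implemented in C++), so fragments and sequences with extra
flanking domains map onto the columns they actually cover. Loop lengths
are counted as record residues between fixed anchor columns, so
insertions inside a loop lengthen it — this is precisely what makes the
long, variable Aquatic loops measurable. A record whose alignment score
falls below the profile floor (default 100 half-bits; family members
score ≈ 300, random sequences ≈ 10) is treated as non-family.

### Plug-motif calibration

Plug presence is a thresholded PSSM score over the 17 motif columns,
evaluated at the mapped motif location with a fallback scan over the final
40 residues. The threshold is calibrated at profile-build time on 1,000
seeded random-shuffle negatives and set at their 99th percentile, so the
false-positive rate on the calibration null is at most 1% by
construction. The calibration is deterministic under the profile seed and
stored with the profile.

## Screening and curation rules

Tabular similarity-search output (the standard 12-column format) is
screened with strict inequalities: a subject is accepted when its best
E-value to a single query is below 1e-05, or below 1e-03 to at least two
distinct queries; only hits covering more than 75% of the query
participate, and subjects supported solely by low-coverage hits are
flagged as fragmentary rather than silently dropped. Curation then
applies, in pipeline order: fragment removal (length < 225 residues, or
< 75% of the reference domain covered, with named exceptions retained and
flagged), greedy redundancy clustering (90% identity by default, 95% for
densely sampled groups; records visited longest-first so complete
sequences become representatives), active-site screening (a record is
divergent when His12, Glu32 and His47 are all nonconservatively replaced
or missing, "nonconservative" operationalised as BLOSUM62 score ≤ 0),
contaminant flagging (> 50% identity to a reference sequence from an
incompatible phylum; identical cross-phylum pairs always flagged), and
evidence-based confidence labels (a taxon group supported by fewer than
two independent data types — e.g. transcriptome only — is low-confidence).

Percent identity is computed from an ends-free global alignment (BLOSUM62,
gap open 10, extend 1) with terminal-overhang columns excluded from the
denominator, so fragments are scored over their overlap; internal gaps
count as mismatches. This is the only reading of a "global" identity that
is consistent with retaining partial-domain representatives, and the test
suite checks it against a brute-force alignment-enumeration oracle.

## Gain/loss reconciliation

Two models connect a family's presence/absence pattern over a rooted
(possibly multifurcating) species tree to evolutionary events:

* **Single-origin (Dollo) loss counting** (`dollo_losses()`): one gain at
  an origin node (the root, or the MRCA of the present tips), and one
  loss for every *maximal* all-absent subtree below it. Maximality makes
  the count minimal among all single-gain explanations; the suite checks
  this against exhaustive enumeration. Each child of a polytomy is an
  independent subtree: *k* all-absent siblings count *k* losses — the
  conservative (maximal-count) convention for unresolved regions.
* **Asymmetric-cost optimisation** (`min_cost_history()`): a two-state
  Sankoff dynamic programme with gain and loss costs; the root prior is
  absent, so a family present at the root is charged one origin gain
  (free in the `gain_cost = Inf` limit, which reproduces the Dollo count
  exactly). Root ties favour absence (gains as late as possible); branch
  ties keep the parental state; the number of co-optimal reconstructions
  is reported so ties are never hidden. `scenario_table()` sweeps the
  cost ratio and shows how inferred gains trade off against losses — the
  quantitative form of the lateral-transfer-versus-loss argument.

Tips with unknown state are excluded by default (dropped from the tree
and listed separately); they can instead be forced absent or present.

The packaged dataset (`example_gainloss_data()`) is a 30-tip phylum/class
level eukaryote consensus tree with ST-like and Aquatic presence
annotations compiled from published genome and transcriptome surveys.
Under the vertical-descent model with the origin at the root it yields 15
ST-like and 18 Aquatic loss events — the quantities recomputed by
`scripts/acceptance.R`:

```{r fig9}
dat <- example_gainloss_data()
dollo_losses(dat$tree, presence_column(dat$presence, "ST"),
             origin_mode = "root", family = "ST")
dollo_losses(dat$tree, presence_column(dat$presence, "Aquatic"),
             origin_mode = "root", family = "Aquatic")
```

The presence matrix is encoded at the displayed taxon resolution;
within-taxon variation (e.g. among anthozoan orders or bdelloid rotifer
genera) would add further losses and is out of scope of this fixture.

## The synthetic-data generator

Every downstream stage is testable offline because the generator plants
the features the analysis detects, at recorded coordinates:

* a fixed 280-residue single-domain architecture (typical for a
  single-domain PLD) with conserved secondary-structure anchor blocks and
  the clade signatures above;
* background framework drawn uniformly from 19 amino acids — cysteine is
  excluded from the background so cysteine topology can never arise by
  chance in a test;
* substitution noise (`mutation_rate`) applied to framework, anchors and
  non-key motif columns, while the planted diagnostic residues (active
  site, loop cysteines, catalytic histidine, plug key columns) are held
  fixed: those residues are conserved by definition of clade membership,
  and the noise models neutral divergence around them. Accuracy of the
  classifier is therefore 100% on noise-free data and degrades only once
  noise erodes the anchors and motif context that the profile alignment
  and plug score depend on;
* planted curation cases: near-duplicate pairs (~98% identity),
  180-residue fragments, cross-phylum contaminant pairs (identical to a
  separate reference record, as contamination references are separate
  inputs in real use), and active-site-divergent variants;
* a hit table whose per-subject scenarios straddle the screening rule's
  accept/reject boundaries, with the expected decision recorded;
* `simulate_dollo()` scenarios: a single gain plus mutually non-nested,
  maximal loss branches chosen by randomized backtracking, so the planted
  scenario is exactly recoverable by `dollo_losses()`.

One integer seed drives everything; per-record substreams are derived
from the record index, and identical configurations produce byte-identical
files.

What the generator does **not** emulate: realistic phylogenetic sequence
evolution (divergence is i.i.d. substitution noise, not a substitution
model on a tree), indel evolution in the framework, compositional bias,
or alignment ambiguity in real homologs. Passing the recovery tests
therefore demonstrates that the implementations are faithful to their
definitions, not that the thresholds are optimal for real data.

## Numerical choices and edge cases

* Coordinates are 1-based and inclusive everywhere, matching the tabular
  search convention.
* All screening thresholds are strict inequalities (`E < cutoff`,
  `coverage > cutoff`); coverage above 1 (gapped alignments) is clamped
  with a warning.
* Redundancy clustering visits records by (length descending, id
  ascending); the tie-break favours complete sequences as
  representatives.
* The DUF-B detector tolerates ±2 residues per inter-cysteine spacing;
  a stretch of +5 on any spacing breaks detection, and the repeat must
  end in a glycine-rich stretch (≥ 3 Gly in six residues) and a tyrosine.
* Problem sizes in the test suite — 200 random trees of ≤ 12 tips against
  exhaustive enumeration, 100 planted gain/loss scenarios, 200-record
  classifier benchmarks, alignment oracles on sequences of length ≤ 6 —
  were chosen so the whole suite enumerates its oracles exactly while
  running in a few minutes.

## Limitations

* The packaged reference profile is synthetic; analyses of real sequences
  should substitute an alignment of real exemplars
  (`build_reference_profile(alignment = ...)`) and recalibrate.
* The βα1-loop gate (`ba1_max`, default 3) is expressed as an absolute
  length because the family consensus loop is constant in the profile; it
  is a parameter, not a claim about all GDPDs.
* Reconciliation ignores branch lengths and uses parsimony, not
  likelihood; it quantifies scenario costs but does not test them
  statistically.
* The monophyly predicate is deterministic; statistical topology tests
  are out of scope.
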