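---
title: "Methods: comparing intronless and multi-exon genes across vertebrate genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing intronless and multi-exon genes across vertebrate genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronless)
```

## The scientific setting

Intronless genes (IGs) — protein-coding nuclear genes whose single transcript
consists of one exon, with no intron anywhere including the untranslated
regions — form a small but functionally distinctive minority of mammalian
genomes (histones, many GPCRs, several bHLH and POU transcription factors,
the β-protocadherin cluster). Because they escape splicing entirely, their
regulation, post-translational repertoire and evolutionary dynamics differ
from multi-exon genes (MEGs). This package implements the computational
chain needed to characterize such genes comparatively: classify architecture
from annotations, infer orthology across a fixed set of seven vertebrates,
reconstruct duplication/loss histories, stratify genes by conservation age,
classify expression changes between two developmental stages, and run the
accompanying enrichment, PTM and synteny statistics.

All comparative steps operate on a fixed, rooted, binary species ladder

```
(((((mouse,rat)Muridae,(human,chimp)Primates)Eutheria,opossum)Theria,chick)Tetrapoda,zebrafish)Vertebrata
```

The internal labels name the clades used for age assignment; `Primates` is
an implementation label for the human/chimp node, which is not itself an age
group.

## Architecture classification

`classify_gene()` applies an ordered cascade so that every gene receives
exactly one call:

1. non-protein-coding biotype → excluded (`non_coding`);
2. mitochondrial contig (configurable name set `{MT, chrM, chrMT}`) →
   excluded (`mitochondrial`);
3. no CDS on any transcript → excluded (`incomplete_annotation`);
4. more than one transcript → MEG (`multi_transcript`); a CDS spread over
   two or more exons → MEG (`multi_exon`);
5. a single transcript whose CDS sits in one exon but which carries further
   (untranslated) exons → MEG (`utr_intron`) — the uiSEG case, an intron in
   a UTR;
6. otherwise IG.

Two design points deserve note. UTR introns are detected from exon/CDS
geometry in the same annotation file rather than by querying an external
intron database: the decision boundary is identical and the package stays
self-contained. And genes whose transcripts disagree are MEGs via the
multi-transcript rule, which matches the definition of an IG as having one
exon *and* one transcript. Mitochondrial curation is mechanical (contig
names); true manual curation is not reproducible in code.

## Orthology

`best_bidirectional_hits()` implements the reciprocal-best-hit rule on
BLAST-tabular records: for each query, the best hits *per target species*
are those with maximal bitscore (ties resolved toward higher identity; exact
ties all kept, so a gene may have several co-orthologs in one species —
needed to represent post-speciation expansions). An undirected edge is
accepted when both directions are mutually best and both reach the 50%
identity threshold, boundary inclusive. The threshold is applied to accepted
pairs rather than as a pre-filter, which makes the edge set monotone in the
threshold — raising it can only remove edges. Whether a coverage filter
should accompany the identity filter is genuinely open; identity-only is the
default, and a coverage column, if present, is simply ignored.

Orthogroups are the connected components of the resulting graph restricted
to non-isolated genes. An optional minimum-cut splitter
(`split_low_density = TRUE`) breaks components whose edge density falls
below a threshold; on the clean, desk-scale data this package targets,
components are exact, so the splitter is off by default.

## From orthology graphs to event trees

A relation in which two genes are orthologous exactly when their last common
ancestor is a speciation is always a **cograph** (no induced four-vertex
path). `is_cograph()` tests this by recursive decomposition — a multi-vertex
module must split into connected components or complement components; a
subset connected in both the graph and its complement is a prime module and
certifies a P4. Graphs of up to 30 vertices run through a compiled bitmask
core; larger graphs use the same recursion in R. The test suite checks the
compiled core against exhaustive induced-P4 search on *every* labeled graph
with up to 7 vertices.

Estimated relations need not be cographs. `cograph_edit()` repairs them
greedily: find all induced P4s, apply the single-edge toggle inside an
offending quadruple that destroys the most P4s (ties prefer deletion over
addition, then the lexicographically smallest pair), repeat. Same-species
edges are never introduced, and the edit set is returned, not hidden. This
heuristic is a documented choice: decomposition-based reconstruction tools
rarely document their behaviour on noisy relations, and minimum cograph
editing is NP-hard, so a transparent greedy rule with a logged edit set is
preferable to an opaque exact search.

`modular_decomposition()` converts a cograph into its canonical cotree
(series/parallel internal nodes, no like-labeled parent–child pairs);
`label_events()` renames series → speciation and parallel → duplication. A
speciation node with the same species on two sides is biologically
impossible; such nodes are flagged inconsistent and reported, never silently
repaired.

## Reconciliation and loss accounting

`reconcile()` embeds each event tree in the ladder by LCA mapping: every
node maps to the lowest ladder node containing all its descendant species.
Losses are read off the embedding: a lineage that silently passes a ladder
speciation loses the off-path side. Concretely, if a node's image and its
child's image are `d` ladder edges apart, the edge implies `d − 1` losses
below a speciation (the speciation itself consumes one step) and `d` below a
duplication (copies start at the duplication's image). Multifurcating
speciation nodes — collapsed chains in the canonical cotree — are resolved
against the ladder by recursively partitioning children according to which
side of the image their own images fall in; this is equivalent to counting
pass-through nodes of the induced (Steiner) subtree of the ladder spanning
the children's images. Duplication nodes of arity *k* count as *k − 1*
duplication events at their image; nested-versus-star duplication histories
are indistinguishable in the orthology relation, so no binarization is
attempted and losses are charged per child from the common image. This
convention is applied uniformly and is exactly mirrored by the simulator's
ground-truth accounting (below).

Ancestor preservation (each child's image descends from its parent's image)
is asserted on every output, and per-clade totals of gains, losses and
lineage presence are aggregated by `summarize_histories()`.

## Ground truth: what the simulator emulates

`simulate_gene_family()` evolves one ancestral gene along the ladder.
On every branch each lineage experiences events of a two-type Poisson
process (duplication rate and loss rate are *expected events per branch per
lineage*; positions uniform via exponential waiting times); surviving
lineages speciate at internal nodes. Architecture (IG/MEG) is inherited,
starting IG with probability `ig_prob` and switching with probability
`switch_prob` per branch traversal. Defaults — duplication 0.3, loss 0.2 per
branch, 4 vs 4 replicates, negative-binomial counts with mean 100 and
dispersion 0.05, 10% planted DE at |log₂FC| = 2, 20% planted not-expressed
genes — are the package's standard study conditions: moderate event rates
that give non-trivial multi-copy families while keeping most families
single-copy, and count parameters typical of a bulk RNA-seq experiment at
this depth.

Each history records three layers of truth: the raw event tree; the true
orthology relation (pairs whose LCA is a speciation — provably P4-free,
asserted exhaustively in tests); and *observable* event counts. The last
deserves emphasis. A duplicated copy whose descendants all died leaves no
trace in any extant data, and copies whose descendants fall into different
connected components of the orthology relation are reconstructed
independently; no method working from the relation can recover such events.
Observable counts are therefore computed by restricting the true tree to
each component of the true relation (plain union-find, not the igraph
route), canonicalizing, and walking the result against the ladder with the
same per-child accounting convention the reconciler uses — but implemented
independently (tree pruning + Steiner-subtree formula versus graph
decomposition + recursive refinement). The validation battery demands exact
equality of the two routes' duplication and loss totals on 500 simulated
families, and gets it, per branch as well as in total.

The emitters produce the concrete files the pipeline ingests. Annotations:
GTF per species, IGs as one exon with an interior CDS, MEGs as three exons
with a spanning CDS, plus optional decoys (mitochondrial, non-coding,
multi-transcript, uiSEG) for the exclusion filters. Similarity: identities
determined by the clade of a pair's LCA (95 down to 75 for orthologous
pairs, 40 for paralogous ones) so that co-orthologs tie exactly and the 50%
threshold separates cleanly; Gaussian jitter with standard deviation
`20 × noise` identity points per direction degrades recovery monotonically.
What the simulator does **not** emulate: actual sequence evolution (no
substitution or indel process — identities are constructed, not aligned),
alignment coverage artefacts, annotation errors beyond the planted decoy
types, expression library-composition biases beyond what the planted DE
itself induces, and assembly-dependent locus coordinates. Green tests
therefore certify the *logic* of every stage against the statistical
structure the analysis assumes, not robustness to real-data noise sources
outside that structure.

## Expression classification

CPM is count / library size × 10⁶ with library sizes defaulting to column
sums. The not-expressed rule is "a gene is expressed iff at least 4 of its 8
samples have count ≥ 5". Prose statements of such floors are notoriously
ambiguous between this reading and its converse, so the converse stays
available via `rule = "literal"`; the default is the reading under which the
shipped class tallies reproduce. An optional CPM cutoff can be layered on
top of the count floor (`cpm_cutoff`), but the count-based rule is the
operative default. Fold changes use pseudo-count ½ on mean CPM (standard
practice; keeps zero-mean genes finite). The per-gene p-value comes from a
pluggable stand-in — Welch t on log₂(CPM + ½) by default, an exact binomial
on pooled counts as the alternative — since full-scale analyses delegate
this step to a dedicated DE engine; what this package commits to are the
classification rules (NE overrides; UP/DN require p ≤ 0.05 and a signed
log₂FC; otherwise NC) and the calibration of the stand-in, which the tests
verify (null UP∪DN rate within 3 binomial standard errors of 5% at 2,000
genes; power ≥ 0.95 for 4-fold changes at dispersion 0.02 — a low-dispersion
regime — with 4 vs 4 replicates). The "strong" DE subset used for
enrichment applies |log₂FC| ≥ 2, configurable.

## Enrichment, PTM and synteny statistics

Term enrichment is the upper-tail hypergeometric probability
P(X ≥ k | N, K, n) via `stats::phyper`, skipping terms absent from the
background, with Benjamini–Hochberg q-values (`stats::p.adjust`; the source
states q-values without naming a procedure, and BH is the field's default).
Only over-representation is reported by default. Tests pin the p-values to
brute-force enumeration of all urn configurations up to N = 12 and check
empirical false-positive calibration on 10,000 random study sets.

PTM prevalence uses the pooled two-proportion z-test, two-sided, no
continuity correction by default (a flag enables it), and no correction
across PTM types — each PTM is judged at α = 0.05 on its own, a deliberate
per-PTM decision rule. "Unique" classes are decided before any test. The
microprotein screen encodes the three defining criteria — short, single
domain, larger multi-domain partner sharing the domain — with explicit
package-level defaults (≤ 250 aa candidate, ≥ 400 aa partner, chosen below
the 200–400 aa mode typical of IG protein lengths); dedicated microprotein
finders use richer homology models, so candidates here are screening
hypotheses under documented thresholds, not assignments.

Synteny reports are deliberately lightweight: matches/losses/expansions by
orthogroup multiset comparison, strand flips per matched pair, and order
inversions as maximal descending runs of matched indices. Locus membership
uses an any-overlap rule. This is adequate for single-locus, paper-scale
comparisons such as the β-protocadherin cluster; genome-wide breakpoint
analysis is out of scope.

## Conservation age

The strict (default) rule is conjunctive, following the cumulative ladder:
rat → Muridae; rat+human+chimp → Eutheria; +opossum → Theria; +chick →
Tetrapoda; +zebrafish → Vertebrata; no orthologs anywhere → mouse-specific.
The alternative `deepest` mode dates a gene by the ladder MRCA of all
species with any ortholog. The two differ on gappy profiles (orthologs in
rat and human but not chimp: Muridae strict, Eutheria deepest); both
conventions occur in practice, so both are shipped and the mode is explicit
in the output. Age assignment is
monotone in both modes, and strict never exceeds deepest — both properties
are tested. When a mouse gene has several orthologs in one species, the
per-genome architecture table classifies it by majority vote with ties to
"Other" (the source states no rule; majority is the least-surprising
default).

## Numerical and engineering choices

* Coordinates are 1-based inclusive end to end (GTF convention), no
  re-basing.
* The identity threshold boundary is inclusive (exactly 50.0 passes).
* Degenerate inputs: zero library sizes, empty graphs, empty clusters,
  zero-total table rows and zero-variance genes all have defined behaviour
  (errors where the input is invalid, explicit zeros/notices where it is
  merely empty).
* Tie-breaks are deterministic everywhere (lexicographic gene ids as the
  last resort), so every stage is bit-reproducible under a fixed seed; the
  pipeline writes a manifest and the test suite compares whole run
  directories byte for byte.
* The cograph core is compiled (Rcpp) because the validation strategy —
  exhaustive sweeps over all 2,097,152 labeled 7-vertex graphs — is not
  feasible in interpreted R; the R fallback above 30 vertices is tested
  against the compiled core on random graphs.
* Problem sizes used by the checks: 500 families for duplication/loss
  recovery, 2,000 genes for DE calibration, 10,000 draws for enrichment
  calibration, exhaustive graphs to 7 vertices and cotrees to 6 — sizes at
  which every property is decisive yet the whole suite runs in about two
  minutes.

## Known limitations

* The cograph edit is greedy, not minimum; on heavily corrupted relations
  it can over-edit (the edit set is always reported for inspection).
* Duplication placement is the children's LCA; earliest-possible placement
  and loss-minimal binarization of multifurcating duplications are not
  attempted, and recovered event counts are defined relative to that
  convention.
* The DE stand-in is not a dispersion-moderated NB test; it is calibrated,
  not optimal, and should be swapped for edgeR/DESeq2 semantics when real
  count data are analyzed.
* Orthogroup splitting by minimum cut is a stand-in for spectral
  clustering and is off by default.
* The microprotein screen's thresholds are package defaults, not inferred
  constants; candidates are screening hypotheses, not assignments.
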