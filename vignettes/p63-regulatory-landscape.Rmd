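---
title: "Dissecting the p63/p53 regulatory landscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the p63/p53 regulatory landscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

p63 (the ΔNp63 isoform) and p53 share a nearly identical DNA-binding
domain and recognise overlapping response elements, yet drive largely
distinct programs: p53 the canonical stress response, ΔNp63 epidermal
identity and squamous cell carcinoma (SCC) growth. Individual perturbation
or ChIP-seq studies of p63 agree poorly with each other, so any credible
description of the p63 gene regulatory network has to integrate *many*
datasets and let agreement across them be the unit of evidence. This
package implements that integration chain as reusable, tested components:

1. a **vote-count meta-analysis** of differential-expression datasets
   (the per-gene *Expression Score*),
2. **consensus integration** of peak sets from many ChIP-seq datasets
   with per-region dataset-support counting,
3. **iterative de novo motif discovery** over high-confidence binding
   sites,
4. **hierarchical classification** of response-element (RE)
   architectures, and
5. multi-evidence **direct-target prediction**.

A synthetic-data generator with fully known ground truth
(`sim_config()`, `simulate_expression()`, `plant_sites()`,
`wire_targets()`, `simulate_inputs()`) stands in for the real corpora so
that every stage is testable offline.

## The Expression Score

For each of K differential-expression datasets (the compiled study
corpus has K = 16: 8 RNA-seq and 8 microarray by default in the
simulator), a gene is called *up* when its BH-adjusted p-value is at or
below `alpha` (default 0.05, boundary inclusive) and its log2
fold-change is positive; *down* symmetrically. The Expression Score is

> score(g) = #datasets calling g up − #datasets calling g down,

computed over the datasets that *cover* g (report it at all). Genes must
be covered by ≥ 3 datasets including ≥ 1 RNA-seq dataset to be scored.
Knockdown-design tables must be sign-oriented before scoring (positive =
higher when p63 is active); `read_de_table(sign_flip=)` does this per
dataset. Design choices the upstream literature leaves open, fixed here:

* **Duplicate gene rows** (multi-mapped array probes) collapse to the
  smallest adjusted p-value — conservative for vote counting.
* **Fold-change floor** defaults to 0; only the p-value gates calls.
* **Median log2 fold-change** is computed over all covering datasets
  (a `median_over = "significant"` switch is provided).
* **Unique ranks** break ties by score, then median fold-change, then
  lexicographic gene id, so a pre-ranked list for enrichment tools is
  reproducible.
* **Sparse extreme score groups** (fewer than 3 genes in an outermost
  group) are merged one step toward zero, iteratively; raw scores are
  preserved, only the group label changes.

## Peak-support integration

Each dataset contributes one consolidated peak list (replicate groups
are reduced to regions covered by ≥ 2 replicates). All peak boundaries
become breakpoints of a sweep-line segmentation (`support_segments()`,
built on `GenomicRanges::disjoin`), and every segment carries the exact
set of datasets covering it. A *binding site*, for thresholding, is a
maximal merged region; its support is the maximal segment support inside
it. Three class sets are built (`build_class_sets()`):

* **shared**: p63 support ≥ 5 *and* p53 support ≥ 5,
* **p53-unique**: p53 support ≥ 5 and *not a single* overlapping p63
  dataset (≥ 1 bp), and symmetrically **p63-unique**;
* regions with 1–4 datasets of the opposite factor fall in neither set —
  the gap is intentional.

Classification happens on one region universe (the merged combined
coverage), which makes the three sets pairwise disjoint by construction.
The per-base correctness of the segmentation is property-tested against
a literal per-base membership count on hundreds of random instances.

## Motif discovery with iterative masking

The response-element grammar: a decameric half-site RRRCWWGYYY
(R = A/G, W = A/T, Y = C/T); a full RE is two adjacent half-sites;
variants insert a 1-bp spacer, truncate to a three-quarter site (full
decamer + half decamer) or a lone half-site. The p63-flavoured full site
relaxes the central WW to NN while keeping the invariant C4/G7 (and
C14/G17) core anchors.

`discover_motif()` is a self-contained engine. For each candidate width
(10, 15, 20, 25 bp):

1. **Seeding.** Candidate words are the most frequent exact window words
   plus a random draw of distinct words (degenerate REs rarely repeat
   exactly). Each candidate is scored by a binomial enrichment of its
   mismatch-tolerant occurrence count (allowance ⌈L/5⌉) against its
   match probability under an order-0 background estimated from the
   input sequences. Selection is deterministic given the seed and
   strand-canonical, so reverse-complementing the corpus yields the
   mirrored motif.
2. **Refinement.** The top seeds are refined by ZOOPS-EM ("zero or one
   occurrence per sequence") with best-site (hard) responsibilities:
   each sequence contributes its best-scoring window on either strand,
   or background. The objective (total assigned log-odds, bits) is kept
   non-decreasing by reverting the last step if it ever drops; a
   full-posterior E-step is intentionally not used — recovery-based
   testing showed the hard variant sufficient and it keeps the objective
   interpretable.
3. **Selection and trimming.** The refined motif with the largest
   objective across widths wins; flanking columns below 0.25 bits of
   information are trimmed.

**Detection threshold.** Each motif's threshold (bits) is
max(background bound, 0.85 × expected site score), capped at the maximal
achievable score. The background bound is computed by dynamic
programming — the exact distribution of window scores under the order-0
background, binned at 0.1 bit — as the smallest score whose tail
probability is ≤ 10⁻³ per scanned window. The specificity floor
references the *expected* score of a site drawn from the motif itself
(raw probabilities, so structurally forbidden bases contribute nothing):
referencing the maximum instead would price genuine degenerate sites out
of detection, because pseudocount-sharpened maxima are scores real sites
never attain. The floor is what lets the hierarchical classifier
separate a three-quarter site from the full-site motif, whose first 15
columns it matches well.

**Iterative masking** (`iterative_discovery()`): discover; if the motif
is p53-family-like, record it as the next tier, remove every sequence
with a match at the detection threshold, repeat. "Family-like"
(`is_family_like()`) is operationalised — the upstream literature
identifies motifs visually — as: some alignment of the half-site
consensus places C and G core anchors (half-site positions 4 and 7) on
columns with probability ≥ 0.5 each, and total information content
≥ 8 bits. The IC floor sits deliberately between what best-site EM can
extract from pure background (≈ 7.5–8 bits of selection bias — each
sequence contributes its best of ~380 windows, about log2(380) bits) and
the weakest genuine RE motifs observed in tier recovery (8.5–12 bits).
The predicate is a single isolated function, easy to replace.

## Architecture classification

Regions are assigned hierarchically (`hierarchical_assign()`): the first
motif in priority order (primary shared motif, then primary
factor-unique motif, then remaining tiers in discovery order) that
matches at its threshold claims the region; each region is counted once;
unmatched regions stay in the denominator as `"none"` (fractions are
reported with and without it).

Motifs are labelled structurally (`label_architecture()`): a CWWG-like
*core* is a position pair with P(C) ≥ 0.5 and P(G) ≥ 0.5 three bases
downstream. Two cores 10 bp apart → full site; 11 bp → 1-bp-spacer site;
a single core with partial-core evidence (a C one half-site downstream,
or a G one half-site upstream, of the partner position) → three-quarter
site; a lone core → half-site; no core → other. Both orientations are
evaluated. The central W positions are deliberately *not* required:
the p63-flavoured grammar (CNNG cores) would fail a W test at exactly
the positions that make it p63-like.

Known mislabeling modes, quantified on planted corpora: ~2% of
three-quarter sites gain a chance full-site completion from background
flanks, and ~3% of half-sites gain a chance partial core — both are
genuine matches of the higher-priority motif, not scanner errors; the
planted-mixture recovery stays within ±0.01 per class at n = 1000.

## Target prediction

A gene is called a high-probability direct target
(`call_targets()`) when |score| ≥ 8 (half the 16-dataset corpus) and it
is linked to a binding site supported by ≥ 10 datasets (half the
20-dataset p63 corpus) through either route:

* **TSS proximity**: ≥ 1 bp of the site within 5 kb of any TSS of the
  gene (boundary inclusive at exactly 5000 bp; distance measured from
  the nearest site boundary to the TSS point; multi-TSS genes qualify
  through any TSS);
* **enhancer linkage**: the site overlaps (≥ 1 bp) an enhancer linked to
  the gene with double-elite status (`require_elite = TRUE`).

A site may evidence several genes (many-to-many, consistent with
enhancer biology). Calls carry both evidence flags and a
direction-matched SCC-set flag (`flag_gene_set()`): a gene called up is
flagged only if the SCC set lists it as up. The packaged published
target table (`inst/extdata/table1_p63_targets.tsv`) is the fixture for
this stage: re-applying the caller to its columns must reproduce its
180-row set (138 up, 42 down; 32 SCC-flagged, 28 up / 4 down) exactly.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the study conditions: 16 expression
datasets (knockdown/overexpression mixtures re-oriented to a common
sign), 20 p63 and 28 p53 ChIP-seq datasets, five RE architectures
planted into an order-0 background genome (41% GC, 1 Mb), a long-tailed
dataset-support distribution (geometric decay 0.85), 200-bp peaks
jittered ±25 bp around sites — peak geometry values typical of ChIP-seq
callers; the upstream literature does not state them. Planted regulation
uses per-dataset detection probability 0.9 and false-positive rate 0.02
by default in recovery tests; coverage is complete except for a planted
2% sparse-coverage fraction so the ≥ 3-dataset rule has something to
exclude. Degenerate bases are sampled uniformly over their IUPAC sets
(consensus strings, not frequency matrices, are what is published).

Not emulated, deliberately: read-level noise (no FASTQ), ChIP
fragment-length effects, replicate-level peak structure (replicate
consolidation is tested on hand-built fixtures), order-1 sequence
composition, and motif-quality/occupancy correlations. Passing recovery
tests therefore demonstrates correctness of the *computational chain*,
not robustness to every artefact of real data. The published real-data
percentages (e.g. ~70% full-length REs under high-confidence peaks)
depend on the 48 public ChIP-seq and 16 expression datasets and are not
reproduced here; the recovery tests cover those computations
qualitatively on synthetic corpora.

## Numerical choices and degenerate inputs

* Log-odds use pseudocount 0.01 per base; probability rows must sum to 1
  within 10⁻⁶ in written motif files, 10⁻⁹ internally.
* The threshold DP bins scores at 0.1 bit.
* Windows containing any N score −∞; peak sequences with > 10% N are
  excluded from motif work; genomes may contain N but only A,C,G,T,N
  are accepted.
* Peaks overrunning chromosome ends are clipped with a warning.
* EM stops on < 10⁻³ objective improvement or 30 iterations,
  returning the best iterate (flagged) on non-convergence; discovery
  refuses corpora under 20 sequences as underpowered.
* Ties: per-sequence best windows break by window order; ranked lists
  break lexicographically; candidate seeds break by count then word.
* BED is the only interval dialect read or written (0-based half-open,
  converted at the boundary to the 1-based GRanges convention);
  1-based interval tables must be pre-converted to BED.

## Problem sizes used by the test-suite and acceptance script

Recovery checks run at: 200 random instances for the per-base
segmentation oracle; 300 sequences × 200 bp, planting rate 0.8, 10 seeds
for full-site motif recovery (mean per-column total-variation distance
vs the planted matrix ≈ 0.08, well under the 0.15 bound); a 220-sequence
two-architecture corpus plus a 120-sequence background corpus for tier
recovery; 1000 regions for the mixture composition; 2000 genes for
expression-score and target recovery. These sizes were chosen as the
smallest at which the binomial/multinomial sampling error is clearly
below each acceptance band.

## Known limitations

* The discovery engine is HOMER-*inspired*, not HOMER: enrichment
  scoring, threshold optimisation and masking differ in detail, so
  motif-for-motif agreement with published HOMER output is not expected.
* Hard-EM extracts ~7.5–8 bits of apparent IC from pure background
  (best-window selection bias); weak genuine motifs near the 8-bit
  family floor can therefore be missed in late tiers.
* Support counting treats datasets as exchangeable votes; no weighting
  by dataset quality or depth.
* The expression meta-analysis is a vote count: effect sizes enter only
  through the ranking tie-break, never the score.
* `run_all()` re-executes all stages; outputs are byte-reproducible
  under a fixed seed, which is what the run manifest records.
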