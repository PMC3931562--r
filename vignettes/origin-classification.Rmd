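---
title: "Separating host, symbiont and contaminant contigs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating host, symbiont and contaminant contigs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiosort)
```

# The problem

A transcriptome assembled from a symbiotic cnidarian is a metatranscriptome:
host transcripts, dinoflagellate transcripts, and smaller amounts of fungal
and bacterial material from the non-sterile culture system all assemble into
one contig set. With no reference genome for either partner, the assignment
of each contig to its organism of origin has to come from the sequence
itself and from homology. `symbiosort` combines three independent signals:

1. **Composition.** The four lineages differ markedly in GC content and in
   codon-usage bias. Codon and amino-acid frequencies are only meaningful in
   the correct reading frame, so they are computed when a strong homology
   hit pins the frame, and contribute zeros otherwise (with an explicit
   `has_frame` indicator so the classifier can tell "no frame" from "frame
   with unusual composition").
2. **Reference-database homology.** The taxon categories of the top five
   hits against a broad annotated protein database, each scored into eight
   categories. Eight rather than four: a hit to a *non-cnidarian* animal or
   a *non-dinoflagellate* alveolate is evidence of a different quality than
   a hit to the host or symbiont lineage itself, and plant hits catch algal
   material that is not dinoflagellate.
3. **Custom-database homology.** The best hit against the pool of labelled
   sequences left over after the training/test split.

A four-class SVM consumes the concatenation of these signals (134 numbers;
the order is a documented, stable contract — see `feature_names()`).

## Leakage exclusion

Hits to the species that supplied the labelled corpora are discarded before
feature computation (`filter_leakage()`). Without this, the classifier can
recognise training species through their own database entries and report
accuracies that will not transfer to a novel assembly. The exclusion list
is a user input, because only the user knows where their training sequences
came from.

# The classifier

Training corpora are sampled **balanced per class within length bins**
(150–300, 300–500, >500 bp), because short contigs carry noisier
compositional estimates and fewer homology hits; balancing prevents the
abundant classes and lengths from dominating the margin, and binning
enables the accuracy report to be stratified by length. An equal-sized,
disjoint test set is drawn the same way; leftovers go to the custom
database pool. With enough labelled data the bin sizes default to
1076/2000/2000 sequences per class (the 150–300 bin is typically the
limiting one in public corpora); the synthetic benchmark uses 134 per bin
per class, which is where the classifier's behaviour stabilises at desk
scale.

One model is trained across all bins — the bins stratify sampling and
reporting, not the decision function. Design choices where the method is
genuinely open:

* **Kernel and regularisation.** RBF kernel with the `1/n_features` width
  heuristic and `C = 1`. The class structure (clusters in composition
  space, plus one-hot homology blocks) is not linearly separable in
  general, which is exactly the case a radial kernel handles; a linear
  kernel is exposed as an option for users who want a faster, more
  interpretable baseline.
* **Scaling.** Features are z-scaled with statistics computed on the
  training set only and frozen into the model (`fit_scaler()` at train
  time, re-applied verbatim at prediction). Re-fitting the scaler on new
  data would silently shift the decision surface; a unit test asserts that
  a train+test scaler is detectably different.
* **Multi-class scheme.** One-vs-one voting (the libsvm default), with the
  aggregated signed decision values reported per class as margins.
* **Top-5 hit encoding.** Positional one-hot blocks (rank 1..5), not an
  order-free category count: the rank of a hit carries information (a
  dinoflagellate top hit outranks a dinoflagellate fifth hit), and the
  positional encoding preserves it at no modelling cost. This is the only
  encoding implemented; a count encoding was considered and rejected to
  keep the feature contract single and stable.
* **Codon features.** Raw codon fractions are the classifier input. RSCU
  (relative synonymous codon usage) is available via
  `codon_usage(..., rscu = TRUE)` for exploratory use; it normalises away
  amino-acid composition, which here is signal, not nuisance, so it is not
  the default.
* Contigs shorter than 150 bp are classifiable but excluded from training
  and reported in an explicit `unbinned` row by `evaluate_by_bin()`.

# Genomic evidence and consensus

Aligning genomic DNA reads from the (aposymbiotic) host to the contigs
gives an orthogonal origin signal: host contigs should recruit reads,
everything else should not. The package consumes the resulting per-library
count table and computes the **raw arithmetic mean** across libraries —
the evidence question is presence, not abundance, so library-size
normalisation would only rescale a threshold that is calibrated on the raw
scale.

The evidence cutoff defaults to a mean of 10 read-pairs, **inclusive**
(mean = 10 counts as evidence): host contigs typically sit around mean
counts of a few hundred while most non-host contigs are exactly zero, so
the decision is insensitive to the exact cutoff across an order of
magnitude. Raising the cutoff can only shrink the evidence-positive set
(a tested monotonicity property).

The consensus rule confirms the classifier's label when call and evidence
agree (cnidarian-with-evidence, non-cnidarian-without) and emits
`ambiguous` otherwise — misclassifications and genuine cross-contamination
both land in `ambiguous` rather than polluting the confirmed sets. The
discordance table reports, per classifier class, the fraction of calls the
evidence contradicts, rounded half-up to one decimal (display convention;
the unrounded ratio is recoverable from the printed counts). An empty
class yields an undefined (`NA`) rate, never a fake 0.

# Contig clustering and unigene arithmetic

Assemblies inflate gene counts: near-identical contigs, isoforms and close
paralogs each get their own contig. Two greedy passes reduce them:

1. `merge_near_identical()`: a contig is absorbed by a longer centroid
   when the best local alignment (either orientation) matches ≥ 99 % of
   the shorter contig's length. Implemented as a match-count bound
   (`matches ≥ 0.99 × shorter length`), which composes the "full coverage
   of the shorter contig" and "99 % identity" conditions into one robust
   predicate that local alignment trimming cannot evade.
2. `cluster_transcripts()`: contigs join a cluster when an alignment
   ≥ 99 % identical over its columns covers ≥ 20 % of **both** contigs'
   lengths. "Both" is the deliberate reading of the coverage rule: with
   "either", a short repeat-bearing fragment would chain unrelated long
   contigs together. Clustering is single-linkage (A–B and B–C clusterable
   puts A, B, C in one cluster even if A–C fails the pair test), matching
   the greedy centroid behaviour of the UCLUST-style tools this replaces;
   a brute-force connected-components oracle confirms the equivalence on
   small fixtures. Contigs are processed in canonical order (descending
   length, then id), so results are independent of input file order. The
   longest member represents each cluster.

Alignments use `Biostrings::pairwiseAlignment` local alignment with
+1/−2/−3 match/mismatch/gap scores — stringent enough that 99 %-identity
decisions are made on essentially gap-free alignments. N never counts as a
match.

`estimate_unigenes()` implements the worst-case assumption that every case
of multiple contigs annotating one accession is a clustering failure, and
that annotated and unannotated contigs fail at the same rate:
`total × distinct accessions / annotated`. On a published-scale example
(22,668 contigs, 7,895 annotated, 5,054 accessions) this gives ≈ 14,511.
Note the formula is deliberately literal; applied to a host-sized example
(26,219 / 16,373 / 9,386) it gives ≈ 15,030, whereas the figure usually
quoted for such data is ~14,500 — the published arithmetic evidently
involved additional unstated adjustments, so the package documents the
formula it computes rather than matching a number it cannot derive.

# qPCR expression arithmetic

Relative expression is `(1 + E)^(−CT)` with primer efficiency `E ∈ (0, 1]`
(1 = perfect doubling; assay efficiencies typically 0.9–1.0) and CT the
critical-threshold cycle. Technical replicates are averaged **on the CT
scale**: each cycle is a factor of `1 + E`, so the CT mean corresponds to
a geometric mean of template amounts, which is the right average for a
log-scale quantity (averaging on the expression scale would overweight
the replicate with the lower CT). Normalisation divides by the geometric
mean of ≥ 2 user-declared reference genes per condition (reference-gene
stability ranking is the user's responsibility; tools like geNorm do it
well and their output is this function's input). Fold-changes are
`log2(symbiotic / aposymbiotic)` of the normalised values.

# The synthetic generator

`taxon_profiles()` + `generate_corpus()` emulate what the classifier
actually exploits in real corpora, and nothing more:

* Per-class codon weights: a seeded random preference vector per class
  (distinct codon-usage signatures), stop codons excluded, exponentially
  tilted in the per-codon G+C count until the expected GC matches the
  class target. Default targets — cnidarian 0.42, dinoflagellate 0.55,
  fungal 0.45, bacterial 0.51 — are plausible spacings chosen for
  benchmark separability, documented as synthetic settings rather than
  biological estimates.
* Lengths uniform within each bin (the open bin capped at 1500 bp), and
  sequences written codon-by-codon in forward frame 0.
* Mock hits: 0–5 per contig (binomial, per-slot probability 0.8), each
  reporting the true category with probability 0.9, frame +1, descending
  bitscores.
* Read counts: negative binomial (mean 200, dispersion 5) per library for
  host contigs; non-host contigs all-zero except a 5 % contamination
  fraction with small counts (mean 5) — enough to exercise the ambiguous
  branch of the consensus rule.

Everything is a pure function of (parameters, seed); regeneration is
byte-identical, and the end-to-end pipeline reproduces its consensus
table byte-for-byte under a fixed configuration.

**What passing on this generator does and does not show.** The synthetic
classes are honestly separable — real corpora have overlapping GC
distributions, horizontally unequal hit coverage, chimeric contigs, and
dinoflagellate peculiarities (spliced leaders, unusual UTRs) that the
generator does not model. Held-out accuracy near 100 % on the benchmark
(~400 train/~400 test per class, the scale used by `scripts/acceptance.R`
and the test suite) demonstrates that the feature pipeline, the training
protocol and the evaluation are wired correctly and that accuracy is not
worse on longer contigs; it does not promise the same accuracy on real
mixed assemblies, where published experience with this class of method is
roughly 95 % on 150–300 bp contigs and > 99 % above 300 bp.

# Numerical conventions and degenerate inputs

* GC content errors on all-N sequences (undefined), and excludes N from
  numerator and denominator otherwise.
* Codons containing N and trailing partial codons are skipped; stop codons
  are excluded from the amino-acid denominator.
* Hit ranking is bitscore-descending with deterministic tie-breaks (lower
  E-value, then subject id); frame inference uses the best qualifying hit
  (bitscore ≥ 50 by default — the conventional "strong hit" line, exposed
  as `min_bitscore`).
* Constant features scale to exactly 0 (scaler substitutes sd 1), so a
  degenerate training column cannot produce NaNs.
* The discordance percentage rounds half-up, not half-even, to match how
  such tables are conventionally printed.

# Limitations

* Only four origins; diatoms, ciliates and other plausible aquarium
  organisms are folded into whatever class they most resemble.
* Homology hit generation, read alignment and BLAST itself are out of
  scope; the package consumes their tabular outputs.
* The greedy clustering is quadratic in contig count and intended for
  desk-scale inputs (thousands of contigs), not full assemblies.
* No probability calibration on the SVM margins; `ambiguous` is the only
  uncertainty channel.
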