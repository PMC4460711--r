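---
title: "Classifying loss- and gain-of-function mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying loss- and gain-of-function mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofgof)
```

## The problem

A point mutation can abolish a protein's native activity (loss of function,
LoF) or confer a new or enhanced one (gain of function, GoF). Given a
mutation described in the literature at the protein level — "the R132H
mutation of IDH1" — can genomic and annotation features predict which of the
two outcomes it has? `lofgof` implements the full analysis chain for that
question:

1. **Mention extraction** — parse mutation mentions out of sentences with a
   deterministic regular-expression grammar (one-letter, three-letter and
   cDNA HGVS-like notations; deletions, insertion/deletions, duplications,
   frameshifts).
2. **Back-mapping** — convert a protein substitution into genomic
   coordinates and codon-level alleles through a coding-exon transcript
   model and the standard genetic code, validating the stated reference
   residue against the genome.
3. **Filtering** — remove records published before a cutoff year, records
   whose stated reference disagrees with the reference genome, and silent
   substitutions (in that order; each record counted once).
4. **Feature assembly** — the six-feature record per mutation: reference
   allele (REF), substituted allele (SUB), mutation type (TYPE), continuous
   functional-impact score (SCORE, binned into neutral/low/medium/high
   grades), subcellular location (SL) and protein domain (PD).
5. **Statistics** — exact hypergeometric enrichment of locations/domains
   against a background, and two-proportion comparisons of the 12 ordered
   allele pairs and the transition/transversion (Ti/Tv) aggregate between
   the two classes.
6. **Classification** — balanced subsampling (100 records per class, 50
   datasets), stratified 5-fold cross-validation repeated 100 times, for
   logistic regression, a 100-tree random forest, and an SVM with a
   normalized polynomial kernel; aggregated into accuracy, sensitivity
   (LoF called LoF), specificity (GoF called GoF) and rank-based AUC.

Because real literature-mined corpora are not redistributable, the package
is verified end to end on a **synthetic-data module** that generates toy
genomes, multi-exon transcripts on both strands, annotation tables and
class-conditional mutations with known generative parameters — plus a
closed-form Bayes-accuracy oracle for the generative model.

## Coordinate model

Transcript models are ordered coding-exon intervals (1-based, inclusive,
genomic plus-strand coordinates) in transcription order; on the minus
strand, transcription order means descending genomic coordinates and exon
contents are reverse-complemented, so the concatenated CDS always reads
5'→3' on the coding strand. Residue `i` occupies CDS offsets `3(i-1)+1 ..
3i`; `codon_at()` maps those offsets to genomic positions (descending on
the minus strand).

Back-mapping chooses, among the codons of the alternate residue, the one at
**minimal Hamming distance** from the reference codon, breaking ties by
lexicographic order of the codon string. The tie-break is arbitrary in
principle but makes the mapping deterministic and therefore testable; the
round-trip property (edit the genome at the reported position, re-extract
the CDS, re-translate, recover the stated residue change) holds for every
generated substitution on both strands. Multi-edit codon changes (Hamming
distance ≥ 2) are retained as variants but carry no single-nucleotide
REF/SUB features.

Allele pairs are reported on the **coding strand** by default: directional
pairs (A→G vs T→C) are strand-dependent, and the biologically meaningful
reading frame is the coding strand's. `allele_strand = "plus"` switches to
genomic plus-strand alleles.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_year` | 2010 | publication-year cutoff in `apply_filters()`; the source protocol is ambiguous between a 2009 and a 2010 cutoff, so the value is exposed rather than hard-coded |
| `thresholds` | 0.8, 1.9, 3.5 | impact-grade cut points (score units), the published functional-impact-score convention; bins closed on the left |
| `allele_strand` | `"coding"` | allele-pair reporting convention |
| `per_class`, `n_sets`, `folds`, `repeats` | 100, 50, 5, 100 | the balanced-resampling CV plan; 25,000 fold results and 5,000 CV runs per classifier, 160-train/40-test folds |
| `rf_trees` | 100 | random-forest size |
| `svm_exponent` | 1 | normalized-polynomial-kernel exponent. An SVM of this kind is usually described either as a linear-boundary classifier or with WEKA's NormalizedPolyKernel default; exponent 1 gives the linear reading (the kernel reduces to cosine similarity), exponent 2 reproduces the WEKA default |

The "propositional binomial" comparison of allele pairs is read as a
two-proportion test: the pooled z-test is the default, with an automatic
fall-back to the exact conditional (Fisher) test whenever a pooled expected
cell count is below 5 (flagged in the result; `verbose = TRUE` reports both
p-values). Enrichment tests are one-sided upper-tail (enrichment), exact,
with no multiple-testing correction by default — raw p-values are the
primary output, a Benjamini–Hochberg column is optional. In `run_pipeline()`
the enrichment sample is counted at gene level (each mutated gene once per
class; unique gene–domain hits for domains), so the sample is a genuine
draw from the annotation background; with user-supplied backgrounds (for
real data: total counts of annotated human proteins and domain
annotations) any unit convention can be used via `enrich_categories()`
directly.

## The synthetic generator

`simulation_config()` fixes, per class: the subtype mix over {missense,
nonsense, deletion, indel, duplication, frameshift}; the distribution over
the 12 ordered coding-strand allele pairs (substitutions only); the
subcellular-location and protein-domain mixes; Gaussian impact-score
parameters; and the publication-year window. Each gene sits on its own toy
chromosome with 2–4 coding exons, a CDS of 60–120 codons (start codon, no
internal stop, one stop), and a 50/50 strand mix; every location × domain
combination is covered by at least one gene, and each gene carries one
domain interval spanning roughly the middle 40% of its protein, so a
sampled "none" domain is realised by a position outside the interval.

Three details keep the generator faithful to its own ground truth:

* **Single-edit achievability** — a sampled allele pair is placed only at a
  CDS position where that coding-strand edit produces the intended subtype;
  gene and pair are resampled (bounded retries) when a region offers no
  site.
* **Recoverability** — the chosen edit must equal the codon that
  back-mapping reconstructs from the residue change (Hamming-minimal,
  lexicographic tie-break). Without this, a protein-notation mention like
  K→N could be generated via AAA→AAT but reconstructed as AAA→AAC, and the
  closed loop over allele pairs would not be exact.
* **Stop-reachable nonsense pairs** — nonsense substitutions draw their
  allele pair from the configured vector restricted (and renormalised) to
  pairs that can reach a stop codon by a single edit, a set enumerated from
  the genetic code.

Sentences render each mutation in rotating fixed templates — one-letter
(`R132H`, `S72*`), three-letter (`Arg132His`, `Trp26Ter`), and cDNA
(`c.76A>T`) notation for substitutions; `del`/`delins`/`ins`/`dup`/`fs`
notations otherwise — exactly one parseable mention per sentence. The
generator emulates the *output* of a literature-mining stage, not its
difficulty: real abstracts contain ambiguous notation, multiple mentions
per sentence and gene-association errors that these templates deliberately
exclude, so a 100% extraction rate here validates the grammar's contract
with the generator, not performance on free text. Impact scores are drawn
directly from class-conditional Gaussians (deduplicated per variant, since
a real impact scorer is deterministic given the variant) rather than
simulated from alignments: the analysis treats the impact score as an
external input, so only its class-conditional distribution matters.

### Study conditions

Three presets fix the study conditions (`preset_config()`):

* **paperlike** — 258 LoF + 129 GoF mutations over 40 genes: missense-heavy
  subtype mixes with nonsense enriched in LoF and deletions in GoF;
  transition-rich LoF allele pairs (Ti ≈ 0.60) versus transversion-leaning
  GoF (Ti ≈ 0.40); nucleus-biased LoF versus cell-membrane-biased GoF
  locations; impact scores N(2.2, 1.2²) versus N(1.2, 1.2²). Closed-form
  Bayes accuracy ≈ 0.79.
* **strong** — 400 + 400 with large separations on every feature family;
  Bayes accuracy ≈ 0.91. Used to check that the best classifier approaches
  the Bayes bound (within 3 percentage points when averaged over the full
  plan).
* **null** — 300 + 300 with identical class-conditional distributions;
  Bayes accuracy exactly 0.5. Used to check that measured accuracy stays at
  chance, i.e. the harness leaks no label information.

The Bayes oracle sums `max_c π_c p(x|c)` exactly over the finite feature
space (type × pair × impact grade × location × domain), with the score
discretized at the grade thresholds and the same nonsense-pair restriction
as the generator. The classifiers see the continuous score, which carries
slightly more information than the grade; the strong preset keeps the score
overlap broad (means 1.5 apart at sd 1.2) so that difference is well under
a percentage point and the discretized oracle remains the effective bound.

## Numerical and design choices

* **Classifier backends** — logistic regression via `stats::glm.fit`
  (rank-deficient columns dropped as zero coefficients), random forest via
  `ranger` with 100 trees, SVM via `e1071::svm`. The normalized polynomial
  kernel `K(x,y) = (x·y)^p / sqrt((x·x)^p (y·y)^p)` is computed exactly as
  a plain polynomial kernel on L2-normalised rows, which keeps the fast
  libsvm path.
* **AUC** — per-fold rank-based (Mann–Whitney, ties counted half), then
  averaged over folds; pooled AUC is the other defensible convention and
  gives slightly different numbers.
* **Seed discipline** — one master seed expands into separate deterministic
  streams for subset composition, fold shuffles, and forest seeds, so any
  single fold is reproducible in isolation and all classifiers see
  identical datasets and folds.
* **One-hot vocabulary** — collected once from the full input before any
  splitting, so train and test folds share an encoding; model fitting only
  ever sees training folds.
* **Degenerate inputs** — empty sentence files produce zero-count reports,
  not errors; a mention whose numeric field overflows is skipped with a
  warning; a gene missing from the location table yields `SL = "unknown"`;
  records without a score are kept for the distribution analyses and
  excluded from classification; exactly tied grade thresholds take the
  upper bin.

## Problem sizes

The test-suite and acceptance runs use corpora of a few hundred to a few
thousand mutations and the full 50 × (100 + 100) × 5-fold × 100-repeat
plan where the protocol's bookkeeping is asserted (25,000 folds per
classifier); convergence checks of the generator use 5,000 mutations per
class; the back-mapping round trip covers ≥ 1,000 substitutions across
both strands. These sizes make every distributional check stable at the
stated tolerances while keeping a complete run in the minutes range on a
single CPU.

## Known limitations

* The mention grammar is a deterministic subset of what a trained
  sequence tagger recognises; it does not attempt gene-name recognition
  (gene association comes from the input table) and drops unparseable or
  position-less mentions with a log entry.
* Only coding substitutions are mapped to alleles; splice-site, UTR and
  intronic variants are out of scope, and multi-transcript genes use the
  first transcript in input order.
* The impact score is an input (or the simple conservation log-ratio
  `conservation_score()` computed from an alignment column); the package
  does not reimplement any published impact-score algorithm.
* Real-data feature vocabularies (locations, domains) are taken from the
  input tables as-is; no normalisation of, e.g., isoform-specific location
  strings is attempted.
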