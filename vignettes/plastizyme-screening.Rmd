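---
title: "Screening metagenomes for plastic-degrading enzymes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metagenomes for plastic-degrading enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Plastic-degrading enzymes ("plastizymes") — PET hydrolases, PHB
depolymerases and their relatives — are rare, taxonomically scattered, and
mostly known from a few hundred experimentally validated sequences.
`plastizymr` screens metagenomic assemblies, genomes or protein sets for
candidate plastizymes by combining two complementary signals: positional
homology to per-polymer seed families (profile hidden Markov models, with a
pairwise-alignment fallback) and a learned decision over fixed-length
protein embeddings (per-polymer classifiers in a precision-oriented and a
recall-oriented mode).  This vignette explains the underlying models, their
assumptions, the tunable parameters, and the design decisions taken where
the design was genuinely open.

## Pipeline overview

For nucleotide input, protein-coding genes are first predicted by an
internal six-frame ORF caller (a deliberate stand-in for a dedicated gene
finder; see *Gene calling*).  Every protein is scored against the profile
HMM of each requested polymer; polymers whose seed sets cannot be aligned
into a profile are screened by Smith–Waterman alignment against the seeds
instead.  Hits must pass three filters taken from common practice with
these tools: E-value strictly below `1e-5`, bit score strictly above 20,
and — for HMM hits only — a composition-bias score strictly below 10% of
the bit score.  Survivors are embedded by mean pooling of per-residue
vectors and, for polymers with a trained model, assigned a per-polymer
probability.  If reads are supplied, per-gene abundances are reported raw
and as CPM, RPKM and TPM.  The outputs are `summary.csv`, `hits.fasta` and
(optionally) `abundance.csv`.

## Profile HMM: architecture and scoring

Profiles are built from seed multiple sequence alignments.  Columns with a
gap fraction below 0.5 become match states (sequences are unweighted; this
keeps the build deterministic and easily testable).  Match and insert
emissions are observed counts smoothed with background-proportional
pseudocounts of total weight `pseudocount_weight` (default 1.0) per
distribution; node transitions (`M→M, M→I, M→D, I→M, I→I, D→M, D→D`) are
estimated from each seed sequence's implied state path with the same
scheme.  The null model is the amino-acid frequency of the seed set itself
(uniform 1/20 below 100 seed residues).

Scoring is local, Plan7-like: an alignment may enter at any match state and
exit from any match state, both with uniform weight $1/L$; residues outside
the aligned region cancel against the null model.  The forward bit score is

$$ S = \log_2 \frac{P(x \mid \text{profile, all local paths})}{P(x \mid \text{null})} $$

computed by dynamic programming in log space (compiled kernels; numerically
stable for sequences up to ~10 kres).  The Viterbi score is the same
recursion with max in place of sum and supplies the alignment envelope.  A
consensus-anchored global mode exists for diagnostics and closed-form
tests.  On tiny instances both scores are verified against exhaustive
enumeration of all state paths to a relative tolerance of 1e-9.  The local
entry/exit weighting is a scoring scheme rather than a strictly normalized
generative model — the same simplification mainstream profile-HMM tools
make in their local modes.

### E-value calibration

E-values are obtained by an explicit calibration step: `n_random`
(default 200, minimum 100) i.i.d. sequences are drawn from the profile's
null background with lengths sampled from `len_distribution`, scored with
the forward recursion, and a Gumbel distribution is fitted to the scores by
maximum likelihood.  Then

$$ P(S) = 1 - \exp\!\big(-e^{-\lambda (S - \mu)}\big), \qquad E = N_{db} \cdot P(S), $$

with $N_{db}$ the number of proteins screened.  A single Gumbel mechanism
is used for forward scores (HMMER fits an exponential tail to forward
scores; the Gumbel keeps one mechanism for both scorers).  This changes
absolute E-values relative to HMMER but preserves the filter semantics the
pipeline depends on; the fitter recovers known parameters from synthetic
Gumbel draws within 5% relative error at n = 5000.

### Composition bias

The bias score guards against hits whose score comes from skewed residue
composition (e.g. low-complexity stretches) rather than positional signal:

$$ B = \max(0,\; S_{\text{null}} - S_{\text{comp}}), $$

where $S_{\text{comp}}$ re-scores the sequence with the null model replaced
by the add-one-smoothed residue composition of the alignment envelope.  A
sequence whose envelope matches the background has $B \approx 0$;
low-complexity envelopes score $B > 0$ and are removed when
$B \ge 0.1\,S$.

## Pairwise fallback and clustering

Polymers whose seeds cannot form an alignment are screened by
Smith–Waterman local alignment (BLOSUM62, gap open 11, extend 1; a gap of
length $g$ costs $11 + g$).  Raw scores convert to bits with the standard
gapped-BLOSUM62 Karlin–Altschul constants ($\lambda = 0.267$,
$K = 0.041$): $S = (\lambda S_{raw} - \ln K)/\ln 2$ and
$E = m\,n\,2^{-S}$.  The bias filter does not apply to this route.  One
hit is reported per (protein, polymer), taking the best-scoring seed.

Seed redundancy removal and the train/test split both use greedy
incremental clustering: sequences sorted by length (ties by id) join the
first representative with identity at or above the threshold (default
0.95), where identity is identical aligned residues over the shorter
sequence length — the CD-HIT convention.  No k-mer prefilter is used; at
seed-set scale (hundreds of sequences) exact alignment against
representatives is affordable and exactly reproducible.

## Embeddings and classifiers

Sequences are preprocessed by trimming terminal ambiguity codes (`X`) and
rejecting any other nonstandard residue.  The default embedder is
deliberately context-free and deterministic: per residue, a one-hot block
over the 20 standard amino acids concatenated with five scaled
physicochemical scalars (Kyte–Doolittle hydropathy/5, net charge at pH 7,
aromaticity flag, polarity flag, monoisotopic mass/200), mean-pooled into a
25-dimensional protein vector.  Mean pooling of a context-free embedder is
permutation-invariant: only residue composition is encoded.  This makes
every downstream test download-free and bit-reproducible; an adapter
contract (`protbert_adapter()`) lets users substitute an external protein
language model (per-residue vectors, special-token rows stripped before
pooling — pooling runs across the sequence length only), and trained models
record the embedder name and refuse mismatched embeddings.

Two prediction modes train one independent binary head per polymer
(one-vs-rest, multi-label labels allowed):

* **default** — gradient-boosted trees (`xgboost`, single-thread for
  determinism), grid over tree depth {3, 5, 7} and learning rate
  {0.05, 0.1, 0.3}, 60 rounds.  No positive up-weighting: under the heavy
  class imbalance typical of this problem the boosted trees stay
  conservative, which is what makes this the precision-oriented mode.
* **sensitive** — a single-hidden-layer network (grid over 64/128 hidden
  units and 0.2/0.3 dropout), ReLU hidden layer, sigmoid output, weighted
  binary cross-entropy with positive-class weight $n_{neg}/n_{pos}$,
  Adam (step 0.01, batch 32), early stopping on validation loss
  (patience 10, best weights restored).  The positive weighting is what
  makes this the recall-oriented mode.

Loss, optimizer and batch size for the network are documented configuration
choices, not claims about any external reference.  Hyperparameter grids are
intentionally small; the point preserved is the procedure (grid search on a
stratified internal validation split, refit on the full training data).

Decision thresholds are strict (`score > t`): 0.5 for benchmark-style
calls, 0.7 for the high-confidence flag in reports.

## Dataset construction

Negatives are mined per run: proteome proteins that pass the full hit
filter against at least one profile become all-zero-label negatives
("distant homologs without demonstrated activity").  The train/test split
assigns whole identity clusters (default 0.95) to one side —
`ceiling(test_fraction × n_clusters)` clusters to test — so no
near-duplicate pair can straddle the split; the realized sequence fraction
is reported rather than forced to 20%.

## Abundance

Reads are counted per gene from SAM/BAM records that are mapped, primary
and non-supplementary; each mate counts as one read, and the read total
$N$ covers mapped reads over the quantified genes.  With count $c_g$ and
length $l_g$ (bp):

$$ \mathrm{CPM} = \frac{c_g}{N}\,10^6,\quad
   \mathrm{RPKM} = \frac{c_g}{(l_g/10^3)(N/10^6)},\quad
   \mathrm{TPM} = \frac{c_g/l_g}{\sum_h c_h/l_h}\,10^6. $$

Quantification runs against the candidate (hit) genes only, so CPM/TPM are
relative to the hit set, not the whole metagenome — a deliberate and
documented interpretation choice matching the pipeline's flow.

## Gene calling

The internal caller reports all maximal start-to-stop ORFs (starts ATG,
GTG, TTG translated as Met; one gene per stop codon, earliest start wins)
of at least `min_aa_len = 30` residues on all six frames; codons containing
`N` break ORFs.  Reported coordinates are 1-based, inclusive, on the
forward strand and include the stop codon.  The 30-residue floor bounds
spurious ORFs while keeping small depolymerase domains.  This caller has no
coding-potential scoring, RBS model or edge-gene handling; it is a
transparent stand-in whose truth tables the tests control exactly, and an
external caller's protein FASTA can be supplied in proteins mode instead.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline needs with known ground
truth:

* `generate_family()` — a consensus drawn from a family-specific skewed
  residue distribution; members mutated into a prescribed identity band
  (verified by `pairwise_identity()`, redrawn until realized identity is in
  band); the MSA is known by construction, so no aligner is involved.
* `generate_metagenome()` — members and non-homologous decoys (drawn from
  the pooled, shuffled family residues) back-translated with uniform
  synonymous codons and planted at recorded coordinates/strands in random
  background DNA, with an in-frame stop guard immediately upstream so the
  ORF caller recovers exactly the planted protein.
* `generate_reads()` — error-free read pairs tiled deterministically to
  each gene's recorded depth, plus a SAM of true alignments; abundance
  assertions are therefore exact, not statistical.  Depth is counted in
  read pairs, so a depth-$d$ gene yields a raw count of $2d$.

These fixtures have no sequencing errors, no codon-usage or GC structure,
no community composition realism, and their negatives are either shuffled
(for the homology screen, where positional signal is what matters) or
drawn from a background composition (for classifier fixtures).  The latter
distinction is forced by the default embedder: because context-free mean
pooling is permutation-invariant, a shuffled sequence embeds identically
to its source and no classifier could separate them — so classifier
fixtures use decoys that differ in composition, which is also the signal a
composition-aware embedder legitimately exploits.  Passing tests therefore
demonstrate the pipeline's mechanics (recovery, filtering, calibration,
reproducibility), not field performance on real metagenomes.

## Numerical choices and degenerate inputs

* All dynamic programming is in log2 space; `-Inf` encodes impossible
  transitions and is handled explicitly by the log-sum-exp.
* Gumbel fitting solves the one-dimensional profile-likelihood equation by
  bracketing (`uniroot`, tolerance 1e-10) with scores centred for
  stability; a zero-variance score set is an error, not a silent fit.
* Zero-denominator metric cases return 0 by convention
  (precision/recall/F1) or 0 for MCC when any marginal is empty; bootstrap
  resamples on which a metric is undefined are skipped and counted.
  Bootstrap inputs are canonicalized by sorting before seeding, making the
  interval invariant to input order.
* Report rows are ordered (sample, polymer, descending bit score, id) with
  radix sorting, so two runs with one seed produce byte-identical CSVs.
* Ties in greedy clustering are broken lexicographically by id; ties in
  the summary by ascending protein id.
* `N = 0` in abundance yields all-zero normalized fields with a warning
  rather than NaN.

## Open design points resolved

* One hit is reported per (protein, polymer) — not per profile — since a
  polymer's screen is the unit users act on.
* Special-token embedding rows are excluded from the pooled mean; pooling
  is across the sequence length only.
* Duplicate protein ids are rejected within a run.
* The read total for normalization covers mapped reads (not all reads).
* Coordinates are 1-based inclusive; all half-open arithmetic is internal.

## Problem sizes

Tests and the acceptance computation run, by choice, at deliberately small
scale: families of 100-residue consensus with 10 members, metagenomes of
~5 contigs of 3–6 kb with 5 decoy genes, calibration with 200 null
sequences of length 80–200, classifier fixtures of 200–300 examples in
10 dimensions, and 1000 bootstrap resamples.  At these sizes every
property asserted is computed exactly or with fixed seeds, and the entire
suite plus the acceptance script complete in a few minutes on one CPU.

## Known limitations

* The default embedder carries no positional or contextual signal; real
  gains from language-model embeddings require an external model through
  the adapter.
* The internal ORF caller will call spurious ORFs in long random stretches
  and misses edge genes; it is not a replacement for a trained gene
  finder on real assemblies.
* Gumbel-calibrated E-values are comparable within a profile and
  calibration, not across tools.
* Multi-hit domain architecture (several envelopes per protein) is not
  modelled; one envelope per protein per polymer.
* Bootstrap resampling is at the protein level, not the cluster level, so
  intervals can be slightly optimistic in the presence of residual
  within-set relatedness.
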