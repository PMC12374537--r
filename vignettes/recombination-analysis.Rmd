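---
title: "Measuring recent homologous recombination from gene-based genome comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring recent homologous recombination from gene-based genome comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Collections of closely related bacterial genomes — isolate genomes or
single-cell amplified genomes (SAGs) from one community — carry a record of
how the population evolves: point mutation slowly pushes genomes apart,
while homologous recombination copies segments between them and pulls the
recombined region back to (near-)identity. Between two genomes at, say, 94%
average nucleotide identity (ANI), a gene that is 99.8–100% identical is
far too similar to be explained by shared ancestry of the rest of the
genome; it was exchanged recently. `recombinr` turns this observation into
a quantitative pipeline:

1. **RBMs**: for each genome pair, find reciprocal best matches between the
   two gene complements (each gene is the other's highest-identity hit).
2. **ANI and F100**: summarise each pair by its gene-based ANI (mean RBM
   identity) and the fraction of RBMs that are 100% identical (F100).
3. **Null model**: compute the fraction of identical genes expected from
   vertical descent alone at that ANI, and test for an excess.
4. **Calls, tracts, r/m**: call individual recently exchanged genes between
   genomes of different genomovars, group them into tracts, test their
   spatial distribution, and estimate how many substitutions recombination
   purged relative to those mutation created (`rm_purged`).
5. **Structure**: cluster genomes into nested ANI tiers (genomovar >98.5%,
   phylogroup >96.5%, species >91%), detect the inter-species ANI gap, and
   summarise cumulative identical-gene fractions by divergence band (A–F).
6. **Sweeps and trees**: partition gene families into alleles, scan for
   gene sweeps (one allele spanning a diverse species), and compare
   neighbour-joining gene trees against the ANI tree.

All user-facing functions take and return tibbles so the stages compose
with the pipe; `run_recombination_pipeline()` chains them end-to-end.

# The null model

The heart of the method is the expectation for the fraction of identical
genes *without* recent recombination. Let `d = 1 - ANI/100` be the pair's
genome-wide divergence and `L` the mean gene length. If substitutions
accumulated uniformly, a gene would be identical with probability
`exp(-d L)` — about `1e-8` at 98% ANI — and essentially no identical genes
would ever be observed. Real genomes are far from uniform: genes differ
enormously in how fast they accumulate substitutions. We model the per-gene
substitution count as Poisson with a gamma-distributed rate multiplier
(shape `alpha`, mean 1) shared by the genome pair:

$$
E[F_{100}] \;=\; E_r\!\left[e^{-r\,dL}\right]
          \;=\; \left(1 + \frac{dL}{\alpha}\right)^{-\alpha}.
$$

Marginally the substitution count is negative binomial, so the expectation
generalises to any identity threshold `tau`:
`P(NB(alpha, dL) <= floor((1 - tau/100) L))` (`expected_f100()`), and a
Monte-Carlo oracle (`simulate_null_f100()`) provides an independent
simulation route against which the closed form is validated in the tests.

With the defaults `L = 900` nt and `alpha = 0.88`, the expectation at 98%
ANI falls in the 6–7% band reported for this class of data; `alpha` is the
single calibration knob, is reported in all outputs, and within the gamma
family is pinned quite tightly by that anchor. The observed excess is
tested with a one-sided exact binomial tail (`f100_excess_test()`), which
treats genes as independent — exactly the null model's own sampling
scheme. In practice the end-to-end test is close to nominal but slightly
conservative for divergent pairs: the measured divergence plugged into the
expectation understates the substitution divergence (fast genes saturate
or fall below the reporting floor), so below ~96% ANI the expectation is
inflated by some tens of percent of itself and rejections become rarer
than nominal. The empirical rejection rate over the 92-99% ANI grid is
measured in the acceptance suite.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.88 | – | gamma shape of per-gene rates; smaller = more heterogeneity |
| `mean_gene_len` | 900 | bp | gene length entering the null model |
| `f100_tau` | 100 | % | identity threshold of the F100 numerator |
| `call_tau` | 99.8 | % | near-identity band for recombination calls |
| `genomovar` | 98.5 | % ANI | same-genomovar threshold; no calls above it |
| `phylogroup` | 96.5 | % ANI | intermediate tier |
| `species` | 91 | % ANI | species tier and constraint-filter floor |
| `ani_floor` | 75 | % | RBM identities below this never enter the ANI mean |
| `min_rbm` | 50 | genes | fewer qualifying RBMs leaves ANI undefined |
| `id_floor` / `min_cov` | 70 / 0.5 | % / – | RBM hit floor (identity / coverage of shorter gene) |

The tier thresholds follow the operational definitions used for SAG
collections with wide intra-species diversity (species at 91% rather than
the canonical 95%); all are arguments, never constants.

# Alignment and RBM engine

Gene pairs are aligned with a glocal (free-end-gap) Needleman–Wunsch
(match +1, mismatch −1, gap −2, linear): global across the overlapping
region, with terminal gaps free and excluded from the reported alignment
length — BLAST-like behaviour on mostly-collinear genes. Internal gap
columns count as mismatches in the identity denominator; N columns are
mismatches. `align_pair()` computes the full matrix; the bulk RBM engine
bands the matrix at `|length difference| + 50 + 2%` of the gene length
(net indel drift in homologous genes rarely exceeds a few percent) and
takes an ungapped fast path for equal-length pairs at ≥97% Hamming
identity, where a gapped alignment cannot plausibly improve on the
diagonal (indel-bearing pairs fall far below the threshold and always take
the full dynamic programme). Candidates are prefiltered by shared 11-mer
counts; a homolog at the 70% identity floor shares ~17 k-mers of a 900-bp
gene, so requiring 8 only discards sub-floor noise. Equality with the
brute-force all-vs-all argmax is asserted against an independently coded
oracle in the tests. Ties are broken by longer alignment, then gene id, so
results are deterministic.

# The synthetic population generator

`generate_population()` creates the study conditions the analysis assumes,
with machine-readable ground truth, so every stage is testable offline:

* **Genealogy**: an explicit tree (root → species → phylogroup → genomovar
  → genome). The default per-species structure (8 genomes: phylogroups of
  2+2, 2, 1, 1 genomovars) populates all divergence bands — within-genomovar
  ANI ~99.2, within-phylogroup ~97, cross-phylogroup ~92–95 with mode ~94,
  inter-species ~87.5 — emulating an intra-species spread of ~92–99.5 and a
  species gap below ~92.
* **Substitutions**: per gene and branch, Poisson(`r_g · t · L_g`) changes
  at distinct random sites, each to one of the three other bases
  (Jukes–Cantor flavoured); the rate multiplier `r_g ~ gamma(alpha, mean 1)`
  is a property of the gene, shared population-wide — slow genes are slow
  everywhere, which is what makes the constraint filter meaningful. A few
  ultra-conserved (rRNA-like) genes get rate multiplier 0.01.
* **Divergence targets** are stated in measured-ANI space and inverted to
  substitution branch lengths through `expected_measured_ani()`, an
  analytic map that integrates over the gamma rates, accounts for
  cross-branch substitution collisions and for the ≥75% reporting floor,
  and includes the binomial spread of per-gene identities. Without this
  inversion the realised inter-species band would drift upward by more
  than a point.
* **Recombination**: events pick a recipient and a donor uniformly within
  the species (any genomovar), a tract start uniform on the contig, and a
  tract length from the mixture 80% Uniform(1, 3) kb + 20% Uniform(3, 20)
  kb; the donor's homologous interval replaces the recipient's (genomes
  share the ancestral coordinate frame; there are no indels). Default rate:
  6.25 events per genome, i.e. 50 per 8-genome species. Truth records every
  event with the genes fully inside its tract.
* **Sweeps**: `inject_sweep()` copies one genome's allele of an operon into
  every species member with a small residual substitution load
  (5×10⁻⁴ per site per copy).
* Gene lengths are lognormal (mean 900, sd 300, min 150 bp) with 100-bp
  spacers, giving ~1.4 Mb genomes; strands are random; a completeness knob
  can drop a random gene fraction per genome (default off). Runs are
  byte-reproducible under a fixed seed.

What the generator does **not** emulate: indels and rearrangements, gene
gain/loss and genomic islands, selection and demography, intergenic
evolution (spacers are shared verbatim across genomes and carry no
signal), and assembly or amplification artefacts of real SAGs. Passing
tests therefore demonstrate the pipeline's behaviour under the stated
evolutionary model, not robustness to structural variation.

# Numerical and design choices

* **ANI dialect**: gene-based (mean RBM identity), not fragment-based.
  One alignment pass serves ANI, F100 and calling; at intra-species
  divergences the two dialects agree closely.
* **Single linkage** operationalises "genomes sharing >X% ANI"; with
  ordered thresholds the genomovar/phylogroup/species tiers nest by
  construction. Band boundaries are half-open downward (an exact 96.5
  falls in C) since strict caption inequalities would leave boundary pairs
  unassigned.
* **Group profiles (A–F)** count *near-identical genes* (identity ≥ 99.8%)
  with union-once semantics, not recombination calls: calls are
  definitionally zero within a genomovar, which would empty group A, while
  the cumulative identical-gene fraction is the quantity that decreases
  smoothly from A to D. E and F are the unions across all genomovars of
  the B and D bands.
* **Gap detection** uses a gaussian kernel density (bandwidth 0.5 ANI
  points, support above the 75% floor); a gap is the widest interval
  between two modes whose valley drops below 25% of the smaller flanking
  peak; peaks under 5% of the global maximum are treated as noise.
* **r/m** is a purged-substitution estimator (`rm_purged`): background
  divergence from non-recombinant RBMs, `r` the substitutions the called
  genes are missing relative to that background, `m` the substitutions
  observed in the background. It is deliberately not a coalescent-model
  r/m and is not expected to match coalescent-based magnitudes.
* **Spatial test**: the statistic is the longest call-free interval (gene
  midpoints, per-contig linear coordinates — no circularity assumed for
  draft genomes); the null re-places the calls uniformly on RBM-bearing
  gene midpoints.
* **Sweep rule**: a family is swept when its dominant allele (single
  linkage at >98.5% identity) covers ≥90% of the species' genomes whose
  carriers span pairs at ≤95% ANI, and the family is not
  constraint-conserved. All three knobs are arguments.
* Degenerate inputs are contracts, not surprises: empty RBM sets give an
  undefined-ANI flag rather than an error; an expected value of 0 or 1 in
  the excess test returns the indicator p-value; zero calls make the
  recombination-free gap the contig length.

# Validation strategy and problem sizes

The test suite validates each operation against an independently coded
oracle (full-matrix alignment, brute-force all-vs-all RBM, exhaustive
topology search with least-squares branch fitting, Monte-Carlo nulls) and
then checks the pipeline end-to-end on simulated populations with known
truth. The end-to-end suites use one default-configuration simulation
(2 species × 8 genomes × 1400 genes, 50 events per species), 200
independent two-genome populations of 400 fixed-length genes for the
type-I calibration of the excess test, and 20+20 replicates of 6 genomes ×
250 genes for the sweep scan; these sizes are the package's validation
choices and are fixed in the tests.

# Known limitations

* **Slow genes mimic recombination.** The 6–7% anchor forces a heavy-tailed
  rate distribution (gamma shape ≈ 0.88), under which roughly a fifth of
  genes evolve at less than 0.2× the average rate. Between genomes at
  93–97% ANI such genes sit in the 99.8–100% identity band *without* any
  recombination — this is precisely why the F100 *excess* over the null,
  not the raw call list, is the quantitative signal. Per-gene calls
  between a single genome pair therefore contain an irreducible
  null-driven component of roughly `n_rbm × expected_f100` false
  positives, and gene-level precision against simulated truth is
  structurally limited at realistic event rates; for the same reason the
  tract-span histogram of raw calls is dominated by single-gene
  (sub-kilobase) runs from null-identical genes rather than by the
  multi-gene planted tracts. Interpret per-pair call lists as candidates;
  interpret the excess test, the A–D gradient, and multi-gene tracts as
  the evidence.
* **Slow genes also mimic sweeps.** A family whose rate is low enough that
  all its members exceed 98.5% identity across the species satisfies the
  sweep rule; the constraint filter only removes the far slower families
  that stay near-identical *between* species. Sweep calls should be read
  as a ranked candidate list (the output is sorted by coverage and
  identity-vs-ANI discrepancy); a rate-aware null for alleles is future
  work.
* **Measured ANI saturates.** Under heavy rate heterogeneity with the ≥75%
  reporting floor, gene-based measured ANI cannot fall much below ~88%
  however divergent the genomes: fast genes drop out of the mean and slow
  genes hold it up. Inter-species bands below that are unattainable in
  this model, and `invert_measured_ani()` says so explicitly.
* The binomial excess test treats genes as independent and is exactly
  calibrated across populations with independently drawn rates; within
  one population, rates are shared, so rejections are correlated across
  pairs of the same collection.
* Tier assignment here is purely ANI-based; real studies may also use
  phylogenies to delimit phylogroups.
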