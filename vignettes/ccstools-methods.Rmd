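---
title: "Methods behind ccstools: signature fitting, trunk tracking, clonal and methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ccstools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccstools)
```

ccstools implements the computational pipeline used to analyse cohorts of
patients who carry many independent skin tumors (the motivating setting is
CYLD cutaneous syndrome): mutational-signature attribution with bootstrap
confidence, mutation sharing across a patient's tumors, clonal
heterogeneity and biallelic tumor-suppressor loss, and differential
methylation between tumor groups. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the field's practice leaves them open.

## The 96-channel substitution catalog

Every somatic single-base substitution is classified by its substitution
class and immediate sequence context. Complementary representations
describe the same event, so mutations with purine reference (A or G) are
reverse-complemented, leaving six classes (C>A, C>G, C>T, T>A, T>C, T>G).
With the 5′ and 3′ flanking bases (4 × 4 contexts) this gives 96 channels.
The channel order is class-major, then 5′ base, then 3′ base,
alphabetically — the layout of version-2 reference signature tables — so
`sbs_channels()[1]` is `A[C>A]A` and `[96]` is `T[T>G]T`. All I/O labels
channels explicitly rather than relying on position.

Only simple A/C/G/T substitutions enter a catalog; indels, multi-nucleotide
variants and records with non-ACGT context are excluded and counted in the
catalog's `n_excluded` attribute, and records whose stated reference
disagrees with the genome FASTA are dropped with a per-table report rather
than silently kept. Coordinates are 1-based (VCF convention). No correction
for exome versus genome trinucleotide composition is applied; catalogs are
fitted on the scale they were observed.

## Signature exposures by non-negative least squares

Given a catalog $c \in \mathbb{Z}_{\ge 0}^{96}$ and a column-stochastic
signature matrix $P \in [0,1]^{96 \times K}$, exposures solve

$$\hat e = \arg\min_{e \ge 0} \lVert c - P e \rVert_2 ,$$

by Lawson–Hanson NNLS on raw counts, so $\hat e_j$ is the number of
mutations attributed to signature $j$. The fit is convex and
deterministic, and on two-signature problems the test suite checks it
against an exhaustive integer grid search over the residual surface. The
generative assumption behind this estimator is that channel counts are a
multinomial draw from the mixture $P f$ of signature distributions — which
is exactly what the catalog simulator produces.

**Bootstrap confidence.** The question the pipeline asks is not "what is
the exposure" but "is this signature present with confidence". Each
bootstrap replicate resamples the sample's mutations with replacement —
because the catalog is a sufficient statistic for channel identity, this
is a multinomial redraw of the 96 counts — and refits. The *exceedance
probability* of a signature is the fraction of replicates in which its
fitted exposure fraction is at least a threshold, default 0.05 (5% of the
sample's mutations). Signatures are ranked by exceedance probability, ties
broken by mean bootstrap exposure fraction and then by signature
identifier (stated so that results are exactly reproducible); the top
$k = 3$ by default are refit alone for the final attribution.
`fit_signatures()` packages the whole procedure as a classed model object
with the usual `print`/`summary`/`coef`/`fitted`/`residuals`/`plot`/
`simulate` methods. Defaults: `threshold = 0.05`, `n_boot = 1000`
(tests and examples use 100–200 for speed), `k = 3`; catalogs under 50
mutations still run but warn that bootstrap confidence is unstable.
Selection is per-sample; to pool a cohort before ranking, sum the catalogs
and fit the pooled catalog.

**Cosine confirmation.** For heavily mutated samples dominated by one
process, the cosine similarity between the raw 96-channel profile and a
reference signature is reported separately (`cosine_similarity()`); it is
scale-invariant and needs no fitting, which makes it the right check when
one process accounts for nearly all mutations.

**Precision of exposure fractions.** How precisely can exposure fractions
be recovered at all? If each mutation's generating signature were
observable, the fraction estimate would have the multinomial standard
error $\sqrt{f(1-f)/n}$. Observing only channel counts loses information:
a Fisher-information calculation for the 96-channel multinomial mixture
(parameters = exposure fractions) shows that, for a 1500-mutation catalog
mixing the CpG, flat and UV signatures at 0.3/0.5/0.2, the Cramér–Rao
bound on any unbiased estimator is 1.25–1.41 times the multinomial
standard error — the flat signature overlaps everything, and NNLS tracks
this bound closely (standardized error spread ≈ 1.4–1.6). Consequently a
"all three fractions within 3 multinomial SEs" event has probability
around 0.9, not 0.95+, for *any* estimator under these conditions; the
acceptance suite asserts the stricter joint property and documents its
outcome rather than relaxing it. Selection of the correct top-3 is far
easier and succeeds essentially always at these sizes.

**The bundled signature matrix is synthetic.** No reference signature
table ships with this package's dependencies, so
`inst/extdata/signatures_96x30_synthetic.tsv` is constructed by
`data-raw/signature_fixture.R`: Signatures 1, 5 and 7 are hand-shaped to
the published qualitative profiles (≈0.66 of Signature.1's mass on the
four NpCpG C>T channels; Signature.7 peaked at T[C>T]T 0.38 and T[C>T]C
0.22 with a dipyrimidine floor; Signature.5 near-flat with a mild T>C
lean), and the remaining 27 columns are seeded sparse random
distributions. It reproduces the layout and conditioning of the real
table, not its numbers; real analyses should load the real table with
`read_signatures()`.

## Trunk and branch mutations across a patient's tumors

`partition_mutations()` groups the union of a patient's mutation keys
(chrom, pos, ref, alt — allele fraction and quality deliberately play no
role) by the exact subset of tumors carrying each key. The trunk (present
in all tumors) implies a common ancestral clone; with three or more
tumors the full presence-pattern partition also exposes internal branches
(shared by a strict subset). "Present" means listed in the tumor's somatic
call set — no re-examination of reads is attempted, since calling is
upstream of this package. `attribute_branch_signatures()` builds a catalog
per group and runs the bootstrap fit; a signature is called present at
exceedance ≥ 0.95 (configurable), and groups under 50 mutations are
flagged low-confidence. `phylo_newick()` writes the star-with-trunk
topology with mutation counts as branch lengths; likelihood-based
phylogeny inference is out of scope.

## Clonal heterogeneity, drivers, and biallelic loss

Deep-sequencing call sets are filtered strictly (`filter == "PASS"` and
`qual >= 100`; the quality rule is read as ≥ 100 because callers cap
quality at 100) or, for microdissected material where calls are confirmed
by read inspection, relaxed to all non-synonymous calls flagged for
review. Each distinct variant key with allele fraction ≥ 0.05 counts as
one mutant clone — the lower bound mirrors the smallest driver VAFs
observable on such panels — and identical variants from different sections
of one tumor are deduplicated; two or more distinct variants in one gene
and tumor constitute clonal heterogeneity. No VAF-clustering deconvolution
is attempted: distinct mutations are equated with distinct clones.

Driver classification follows the cancer-gene-census convention:
inactivating mutations (nonsense, frameshift, essential splice) in tumor
suppressors are drivers; tumor-suppressor missense and any oncogene
mutation require recurrence (default ≥ 3 occurrences in a supplied
frequency table — the threshold is a package decision, exposed as
`recurrence_min`); synonymous changes never are. Gene roles and recurrence
come from plain TSV inputs so nothing depends on an online database.

Biallelic loss of a germline-mutated tumor suppressor is called LOH when
allele-specific copy-number segments covering the gene all have minor
allele 0 (including copy-neutral LOH, major 2 / minor 0); a covering
segment split into pieces with identical allele counts behaves like the
unsplit segment, and discordant minor alleles across the gene produce an
ambiguous-LOH note rather than an error. Failing LOH, a qualifying somatic
mutation on top of the germline allele is a second somatic hit; otherwise
neither.

## Methylation: variable probes, clustering, DMRs

β-values (fraction methylated, in [0, 1]) are analysed directly since the
thresholds of interest are stated in β; probes are ranked by standard
deviation across samples (denominator n − 1) and the top 500 by default
feed Euclidean-distance, complete-linkage hierarchical clustering of
samples. Per-probe differences between the resulting groups use a Welch
two-sample t-test (vectorized row-wise; verified against `stats::t.test`
probe by probe in the tests), unadjusted by default because the region
caller consumes raw p < 0.05 — a Benjamini–Hochberg option exists and is
off by default. Zero-variance probes return p = 1 with a flag so
array-wide scans never abort.

Region calling is a deterministic contiguity rule rather than a smoothing
bump-hunter: a probe is significant if p < 0.05 and |Δβ| ≥ 0.2; maximal
runs of consecutive significant probes with a common sign, gaps ≤ 1 kb,
and ≥ 3 probes become DMRs, labelled hypo when the designated group is
less methylated. The defaults `delta_min = 0.2` and `min_probes = 3` are
package decisions chosen so that planted-truth recovery is exact and every
parameter is testable; all are configurable. Smoothing-based callers on
real arrays will not match these counts region-for-region — this rule
trades their sensitivity near boundaries for full determinism.

## The synthetic-data generators

Each `simulate_*` function is seeded, restores the caller's RNG state, and
returns a `truth` object (serializable with `write_truth()`) holding its
scenario, parameters and planted ground truth, so tests read expectations
from the generator rather than from constants. What they emulate, and
deliberately do not:

- `simulate_catalog()` draws channel counts multinomially from a signature
  mixture — the exact model the fitter assumes. Real catalogs add context
  biases (capture composition, coverage) that this omits, so passing
  recovery tests shows estimator correctness, not robustness to
  model misspecification.
- `simulate_patient_phylogeny()` plants a trunk shared by all tumors plus
  private sets (defaults: 3 tumors, trunk 1848, UV-dominated trunk mixture
  0.7/0.3 against a non-UV private mixture), with distinct positions drawn
  from a toy genome of 24 × 10 Mb contigs and contexts drawn from the
  mixture directly — this avoids shipping a reference FASTA while still
  exercising catalog construction; an optional toy-FASTA path exercises
  `fetch_context()`. No subclonal structure within a tumor is simulated.
- `simulate_deep_seq_vafs()` draws per-variant depth as Poisson (mean
  500×, so the quality filter path sees both PASS and fail records) and
  alt reads binomially; the reported VAF is exactly alt/depth. Sequencing
  error and strand artifacts are not modelled.
- `simulate_methylation()` produces a bimodal β background (equal mixture
  of Beta(2,10) and Beta(10,2)), plants non-overlapping regions whose
  designated-group mean drops by Δβ = 0.4, adds Gaussian noise (sd 0.05,
  the visual scale of replicate scatter on such arrays), and truncates to
  [0, 1]. Planted-region probes draw their background from the methylated
  component: a hypomethylation event must start from a methylated locus,
  and a −0.4 shift from a low background would truncate to 0 and erase the
  planted effect. Probes are evenly spaced (300 bp) and regions separated
  by more than the caller's 1 kb gap limit, honouring the caller's
  contiguity assumptions; probe-wise spatial correlation of real arrays is
  not modelled. Truncation (not renormalization) keeps β in range because
  it is simple and testable.

## Problem sizes and numerical choices

The test suite runs the study-scale scenarios directly: 100-seed cosine
confirmation at 1287 and 375 mutations, 100-seed selection/recovery at
1500 mutations with 200 bootstrap replicates, a 1848-mutation trunk among
three lesions, and 1512 planted 3-probe regions among 100,000 probes —
sizes chosen to mirror the cohort quantities the pipeline is designed
around while keeping a full run in the order of a minute. Ties in
signature ranking and probe selection have stated deterministic breaks;
all stochastic stages rerun byte-identically under a fixed seed (checked
by serializing entire result objects). NNLS needs no initialisation or
tolerance tuning; the grid-search cross-check agrees to within one
mutation of grid step.

## Known limitations

- The bundled signature matrix is synthetic; conclusions about real tumors
  require the real reference table.
- Exposure fractions carry irreducible uncertainty beyond multinomial
  noise when flat signatures are involved (see the Cramér–Rao discussion);
  report exceedance probabilities, not point fractions, for presence
  claims.
- The DMR rule is deterministic and unsmoothed; counts are not comparable
  to bump-hunting callers on real arrays.
- Trunk definition is presence-in-all; with incomplete per-tumor
  sensitivity, real shared counts are lower bounds.
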