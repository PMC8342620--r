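---
title: "Spatial eQTL mapping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial eQTL mapping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtl3d)
```

# Overview

`eqtl3d` maps trait-associated variants to candidate target genes by
requiring two independent lines of evidence per SNP–gene pair: a physical
Hi-C contact between the SNP's restriction fragment and a fragment of the
gene, and a statistical association between the SNP's genotype and the
gene's expression. This vignette records the models behind each stage, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open.

# The coordinate backbone: restriction fragments

All spatial reasoning happens on the partition of the genome induced by a
restriction enzyme. `digest_genome()` cuts at every forward-strand
occurrence of the motif (default `AAGCTT` with cut offset 1, i.e. HindIII's
`A^AGCTT`). Two conventions are fixed once and used everywhere:

* internal fragment coordinates are 0-based half-open (BED-compatible);
  VCF and GTF inputs, which are 1-based, are converted at the boundary;
* fragment ids are global integers in genome order, the stable join key
  between the contact index, the pairing stage and the outputs.

HindIII's site is palindromic, so a forward-strand scan is lossless. For a
non-palindromic enzyme the reverse-complement motif would have to be
scanned too; `digest_genome()` documents this rather than guessing.
Ambiguous bases never match. A SNP falling exactly on a cut boundary is
assigned to the fragment whose half-open interval contains its 0-based
position — effectively the left fragment receives its own last base. This
is an arbitrary but deterministic convention; nothing downstream depends
on which side wins, only on the assignment being unique.

# Hi-C contacts

`read_contacts()` parses Juicer-style `merged_nodups` text and keeps a
record only when **both** ends have mapq ≥ 30 (the usual cleaned-library
rule; the threshold is an argument). Library-level inclusion uses three
strict inequalities — > 90% alignable unique read pairs, > 50% unique
contacts, < 40% duplication — in `library_qc()`.

`build_interaction_index()` recomputes each end's fragment from its
chromosome and position and errors if the file's own `frag` fields
disagree. This makes synthetic and real files mutually checkable: a contact
file is either internally consistent with the genome it claims to describe
or it is rejected loudly.

Self-fragment contacts (both ends on one fragment) are dropped by default.
These are dominated by self-ligation artifacts; the flag `exclude_self`
restores them if a caller disagrees. A consequence worth stating
prominently: a gene overlapping the SNP's *own* fragment is never paired
through a self-contact — it can still be paired through a genuine contact
between two distinct fragments (e.g. the SNP's fragment and the gene's
second fragment). This is an interpretive choice; the alternative (counting
self-contacts) inflates candidate sets with every gene that happens to
share a ~4 kb fragment with a SNP.

A minimum summed contact count per pair is exposed (`min_contacts`,
default 1): whether spatial support should require more than one read pair
is a judgement call, so the weakest defensible threshold is the default and
stricter ones are one argument away.
Intra- and inter-chromosomal contacts are both retained; cis/trans is
decided at the association stage, not here.

# eQTL mapping

## Genotype QC

Variants pass QC when the exact Hardy–Weinberg test p is ≥ 1e-6, minor
allele frequency ≥ 0.01 and missing-call fraction ≤ 0.05 (all arguments).
The HWE test is the exact conditional test — the two-sided p sums the
probabilities of all heterozygote counts whose conditional probability
(given allele counts) does not exceed the observed one — rather than the
chi-square approximation, which misbehaves at the small genotype counts a
compact cohort produces. The implementation enumerates heterozygote counts
of matching parity in log space; the test suite checks it against an
independently-written enumeration for every table up to n = 100.

## Expression preparation

The expression pipeline mirrors the standard eQTL-discovery recipe:

1. gene filters: ≥ 0.1 TPM in ≥ 20% of samples **and** ≥ 6 unnormalized
   reads in ≥ 20% of samples (fraction comparisons are ≥);
2. TMM scaling factors on the filtered counts (edgeR's implementation;
   reference sample = upper quartile closest to the mean upper quartile,
   trims 30% on M and 5% on A);
3. a rank-based inverse normal transform per gene across samples, at
   offset 0.5: `qnorm((rank − 0.5)/n)`, ties by average rank.

The INT offset is a convention, not a discovery; 0.5 is used because it is
symmetric and exact for ties. After INT, effect sizes are in units of
within-gene expression SD, which is how planted effects are specified in
the generator.

## Association model

Each spatial pair is tested by ordinary least squares:

y = α + β·g + Γ·C + ε

with y the inverse-normal expression, g the alternate-allele dosage
(0/1/2), and C the covariates: measured covariates (sex, platform,
simulated confounders in the synthetic data) plus the top genotype
principal components (default 5) and top expression principal components
(default 5). Expression PCs stand in for latent-factor methods (PEER-like
factor estimation is out of scope); both counts are arguments. The p value
for β is two-sided from the t distribution on the residual degrees of
freedom (n − k − 2 for k covariates). Missing dosages are removed pairwise
per test — no imputation — with a floor of 10 usable samples.

FDR is controlled by Benjamini–Hochberg applied **once across all tested
pairs in a tissue**, cis and trans pooled. Pooling is the simplest scheme
consistent with reporting a single FDR < 0.05 discovery set per tissue,
and both the threshold and the grouping are visible in the code rather
than buried; per-stratum adjustment is a config change, not a rewrite.
Cis means same chromosome and within 1 Mb of the annotated gene start
(inclusive); everything else, including cross-chromosome pairs, is trans.

# Annotation statistics

Two resampling conventions coexist deliberately:

* `permutation_enrichment()` (chromatin states) uses the permutation-test
  convention p = (k + 1)/(n_perm + 1), so the minimum attainable p is
  1/(n_perm + 1) — the convention of permutation region tests.
* `bootstrap_overlap()` (trait overlap) uses the bootstrap formula
  p = k/n exactly, with no +1 correction, because that is the stated
  resampling arithmetic it implements; a result of 0 means "below 1/n"
  and the output carries `p_floor = 1/n` to keep that readable.

Bootstrap resampling is with replacement (that is what bootstrap means);
a `replace = FALSE` flag exists for users who prefer permutation-style
draws. Resampled duplicates count once in the overlap. The permutation
universe defaults to the full GWAS table the SNP set came from;
region-permutation tools offer several randomisation strategies
(circularisation, region resampling), and of these, resampling from the
SNP universe is the one implemented — it is named as such in the output.

SNP-to-state assignment uses the point position only (1-based, converted
to 0-based); a state track that tiles the genome assigns every SNP exactly
once, and SNPs outside coverage are counted under `"uncovered"` rather
than silently dropped. Loss-of-function intolerance uses pLI with a strict
threshold: intolerant iff pLI > 0.9.

# Networks

STRING-style edges are kept at combined score ≥ 400, the two stored
orientations collapse to one undirected edge, and protein-to-gene mapping
keeps the maximum score when several protein pairs collapse onto one gene
pair (the mapping loses specificity; max is the conservative choice for
"is there an interaction"). A tissue network keeps nodes with TPM > 0 in
that tissue and edges with both endpoints surviving; clustering is
unweighted Louvain (edge scores are available but node "size" by
expression is presentation, not topology — weighting is exposed as a
future option rather than silently applied).

Louvain is greedy modularity maximisation: deterministic under a fixed
seed, not globally optimal in general. On small modular graphs (bridged
cliques and similar) it attains the exhaustive maximum over all partitions,
which the test suite verifies up to 8 nodes; on structures like rings it
can stop short of the optimum — a known property of the algorithm, not of
this implementation. Reported modularity is always recomputable from the
returned partition, and the tests recompute it independently.

Module over-representation is the upper-tail hypergeometric p
(P(X ≥ k)) per module × pathway cell, BH-adjusted across the whole grid.
The grid-wide adjustment is a deliberate choice: adjusting within modules
would be anti-conservative when modules are many.

# The synthetic-data generator

The generator exists so that every downstream stage can be tested against
planted truth without access-controlled data. Its defaults are the
package's study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 300 kb | smallest genome with non-trivial cis/trans structure |
| site density | 0.25 / kb | a six-base cutter's 4⁶ ≈ 4 kb expectation |
| genes | 60 (0.5–3 kb) | enough for filters, pathways and modules to bite |
| study SNPs | 40 (+200 background GWAS SNPs) | desk-scale analogue of a few hundred catalog SNPs |
| samples / tissue | 120 | between the motivating cohorts' 219 and a small tissue panel |
| MAF | U(0.1, 0.5) | the common-variant genotype floor |
| planted eQTLs | 10: 4 fetal, 3 adult, 3 shared; |β| = 1 SD | reproduces the fetal-heavy asymmetry and shared-set logic |
| planted contacts | 6 high-mapq records per planted pair, + 5 effect-free pairs | effect-free spatial pairs give the FDR real nulls |
| background contacts | 0.002 / fragment pair | sparse uniform noise |
| decoy records | 10% at sub-threshold mapq | exercises the parser's filter |
| missing genotypes | 2% | typical array missingness |

Mechanics worth knowing:

* **Genome**: random sequence with motifs embedded at Poisson-sampled
  positions; accidental motifs from the random background are repaired
  away, so the companion fragment table (built from the planted cut
  positions, independently of `digest_genome()`) is exact, and the two
  paths cross-check each other in the tests.
* **Expression**: latent per-gene expression is y = β·g + Γ·C + ε with
  ε ~ N(0,1); TPM is a gene baseline times 2^(0.5·y) — monotone in y, so
  the rank-based INT recovers the planted effect exactly — and counts are
  TPM × a fixed per-sample library size, rounded, keeping counts
  consistent with TPM ranks while letting both gene filters operate.
  About 10% of genes are near-silent so the filters have work to do;
  planted eQTL genes are never silenced.
* **Placement constraints**: a planted SNP never sits on a fragment of its
  partner gene (otherwise only an excluded self-contact could join them),
  and every planted contact joins the SNP's fragment to a distinct
  fragment of the gene.
* **Determinism**: every stage draws from a seed derived deterministically
  from the master seed, and identical configs produce byte-identical
  output files.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: linkage disequilibrium between SNPs (each
variant is independent), population structure, distance-dependent Hi-C
background (background contacts are uniform over fragment pairs — the noise
structure of real libraries decays with genomic distance), sequencing-level
count noise (counts are deterministic given TPM), and realistic pathway
overlap structure. Results on synthetic data validate the *machinery* —
joins, statistics, conventions, error handling — not the biology.

One power note: the planted chromatin-state enrichment (planted eQTL SNPs
placed in a 2%-share state at 5× its share) concerns only ~10 SNPs, so the
end-to-end permutation p for that state fluctuates widely across seeds.
At this scale that test is honest but weak; the enrichment machinery
itself is validated by unit tests with concentrated SNP sets, where the
expected p equals the +1-convention floor.

# Problem sizes used by the tests

The default test run simulates: 100 toy genomes for the digestion oracle;
spatial-pairing brute-force instances up to 50 SNPs × 50 genes × 500
contacts; 50 replicates × 1000 null pairs at n = 200 for calibration and
50 replicates of a planted 1-SD effect at MAF 0.3, n = 200 for power;
exhaustive HWE enumeration for all genotype tables up to n = 100;
exhaustive modularity maximisation on graphs up to 8 nodes (4140
partitions); and one full end-to-end study at the default configuration.
These sizes were chosen to make every oracle exact or tightly bounded
while keeping the suite comfortably interactive.

# Known limitations

* Louvain optimality is only verified on small modular graphs; large-graph
  partitions are heuristic, as with any Louvain user.
* The cis window is anchored at the annotated gene start (strand-agnostic
  left end), not the TSS; for the synthetic annotation the two coincide.
* Pairwise deletion of missing dosages means different pairs can use
  slightly different sample sets; with ≤ 5% missingness the effect on
  power is negligible, but the per-test n is reported so it is auditable.
* The Fisher comparison of tissue proportions treats the two tissues'
  SNP sets as independent samples; the motivating design uses the same
  SNPs in both tissues, so the test is a descriptive contrast there, and
  it is reported as such.
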