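---
title: "Codon usage bias in plastid genomes: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias in plastid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcub)
```

## The problem

Synonymous codons for the same amino acid are used unevenly. Two forces
shape that unevenness: compositional mutation pressure, which drags all
codon positions toward a genome's equilibrium GC content, and translational
selection, which favours particular codons independently of composition.
Plastid genomes are a classic arena for separating the two, because their
genes share one polymerase, one compositional environment and (in grasses)
strict maternal inheritance. `plastcub` implements the per-gene indices and
cross-gene diagnostics used for this separation, as pipeable functions over
tibbles.

## Model and indices

All statistics operate on per-gene codon counts over a genetic code table
(`genetic_code()`, default NCBI translation table 11 — the
bacterial/plastid code used in chloroplast CDS annotation; its
codon-to-amino-acid map coincides with the standard code). Met (AUG) and
Trp (UGG) are single-codon families and stop codons encode nothing, so 59
"analyzable" codons remain. Terminal stop codons are excluded from all
counts by default (`remove_terminal_stop = TRUE`); triplets containing
ambiguity letters are skipped and tallied.

**RSCU.** `RSCU_ij = X_ij / ((1/n_i) Σ_j X_ij)`. Zero counts are replaced
by 0.5 *before* the computation. This is the conventional zero-substitution
and it has a useful algebraic property: family sums still equal the
degeneracy `n_i` exactly, which the tests exploit as an invariant. The
substitution is applied inside RSCU (and hence CAI weights) only; raw
counts are used everywhere else.

**SCUO.** Per family, `1 − H_i / log2(n_i)` with Shannon entropy
`H_i = −Σ p log2 p` and the convention `0 · log 0 = 0`. The gene value is
the *unweighted* mean over multi-codon families with at least one
observation — not the amino-acid-frequency-weighted variant found in the
older entropy literature. Families never observed in a gene are excluded
from the average rather than counted as maximally ordered. A genome-level
SCUO can be taken either as the mean of per-gene values (our default
reading) or by pooling counts first (`scuo(pool_counts(counts))`); both are
one call.

**Observed ENC.** Only the *expected* ENC has a closed form, so an
estimator is needed for the observed value. We use Wright's: per-family
homozygosity `F̂ = (nΣp² − 1)/(n − 1)`, averaged within degeneracy classes,
then `ENC = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6`. Families with `n < 2` or
`F̂ = 0` are unusable. The single 3-fold family (Ile) is imputed as
`(F̄2 + F̄4)/2` when missing, mirroring the convention of the classic
CodonW implementation; any other empty class leaves the gene's ENC
undefined and flagged rather than guessed. Equal-usage finite samples
overshoot 61 slightly (the estimator is unbiased in `F`, not in `1/F`), so
the reported value is capped into [20, 61] with the raw value kept
alongside.

**Expected ENC and the ENC-ratio.** `ENC* = 2 + GC3 + 29/(GC3² + (1−GC3)²)`
is the null curve under composition alone. We evaluate it at GC3 over *all*
third positions, not synonymous-only GC3s, because the null formula is
written in GC3; gene-level ENC-ratios `(ENC* − ENC)/ENC*` inside ±0.05 are
classified mutation-driven, outside selection-driven, and genes with
ENC > 45 are counted as weakly biased. All three thresholds are arguments.

**CAI and the expression proxy.** CAI follows the Sharp–Li construction:
reference relative adaptiveness `w_ij = RSCU_ij / max_j RSCU_ij`, gene CAI
= count-weighted geometric mean of `w`. The reference set is the analysis'
single unavoidable free choice: with no expression data there is no
canonical high-expression library, so the default reference is the taxon's
own pooled filtered CDS — the most reproducible self-contained option — and
any user-supplied count table or RSCU vector can replace it. The `milc`
column is defined as exactly `1 − CAI` and used as the expression proxy
(higher = more expressed). That equality is a deliberate convention of the
analysis tradition this package implements; it is *not* the
Supek–Vlahoviček MILC statistic, and the documentation says so wherever
the value appears.

## Quality filtering

`filter_cds()` applies rules in a fixed order — frame, minimum length
(300 bp), duplicates, ATG start, terminal stop, internal stops — and
attributes every rejection to its *first* failing rule, so reports are
reproducible and order-insensitive re-runs are idempotent. Two readings of
"removing duplicates" exist; we default to exact nucleotide-string
duplicates (first occurrence kept) because plastomes legitimately carry
identical IR-duplicated genes and string equality is the only reproducible
criterion, with gene-name deduplication behind an option. "Abnormal
termination" is read as: the final triplet must be a stop codon of the
active code. The frame category (length not divisible by 3) is checked
first because every later rule presupposes a codon structure.

## Selection diagnostics

The **PR2 plot** places each gene at `(G3/(G3+C3), A3/(A3+T3))`; (0.5, 0.5)
is the strand-parity expectation under mutation alone. Genes with a zero
denominator are flagged undefined on that axis, not silently dropped. The
**neutrality plot** regresses GC12 on GC3 by OLS; slope near 1 means all
positions drift together (mutation), near 0 means positions 1–2 are held
fixed while GC3 drifts (selection). Genes exactly on the y = x diagonal
count as "above" it (documented tie-break). **Correlation tables** report
Pearson r with two-tailed p from the exact t transform on n − 2 degrees of
freedom and 0.05/0.01 stars; no multiple-testing correction is applied,
matching standard practice for these descriptive tables.

## Optimal codons

High/low-expression libraries are the under-specified step of the standard
recipe: no metric or tail size is canonical. We rank by the package's own
expression proxy (`milc`) and take 10% tails with a floor of 5 genes, ties
broken by gene id; metric, fraction and floor are arguments. Counts are
*pooled* within each library before RSCU (per-gene-mean RSCU is the main
alternative; pooling weights genes by length, which matches how reference
sets are normally built). A codon is optimal when
`ΔRSCU = RSCU_high − RSCU_low ≥ 0.08` and `RSCU_high ≥ 1` — the `≥ 1`
condition is applied to the high-expression library, the natural reading
for a codon that is "optimal" — with star tiers at 0.08/0.3/0.5.
Consequence of the free library construction: the *number* of optimal
codons is construction-sensitive and should be treated as range-level, not
exact, when comparing against published counts.

## The synthetic generator: what it emulates, and what a green test means

`generate_cds_set()` draws each gene as ATG + i.i.d. codons + one stop.
Defaults state a filtered plastome-like world: 60 genes, total lengths
uniform over multiples of 3 in [300, 4500] nt, amino acids uniform over the
20 (under the family-structured regimes). Four regimes:

- `uniform` — no bias; pooled RSCU tends to 1 everywhere.
- `at_biased` — every A/U-ending codon gets within-family weight 3,
  identically in all genes.
- `mutation_gradient` — per-gene pressure `g ~ U(0.2, 0.8)`; every sense
  codon is weighted by `Π (g if G/C else 1 − g)` over its three bases, so
  GC1, GC2 and GC3 track `g` jointly and the neutrality slope tends to 1
  with genes hugging the expected-ENC curve.
- `selection_regime` — the `at_biased` mechanism read as selection: a fixed
  preferred set favoured in all genes while position-1/2 composition stays
  fixed, so GC12 decouples from GC3 (slope ≈ 0) and genes sit below the
  curve.

`regime_truth()` exposes the recovery bands ([0.7, 1.1] and [−0.1, 0.25])
that the acceptance tests check at n = 100 genes.

What the generator does **not** emulate: realistic amino-acid composition,
within-gene heterogeneity, length–function correlation, IR duplication, or
any phylogenetic structure. A green recovery test therefore establishes
that the diagnostics respond correctly to cleanly separated forces — not
that they are well-calibrated on real plastomes, where both forces mix.

One sampling fact deserves emphasis because it bounds what small libraries
can show: pooled RSCU has sampling standard deviation ≈ `1/√n_family` per
2-fold codon (larger for 6-fold families). Ten-percent tails of a 60-gene
set pool only ~5–10 genes, giving ΔRSCU noise of 0.07–0.13 — comfortably
above the 0.08 optimal-codon threshold. An unbiased (uniform) taxon at this
scale therefore yields a *non-empty* optimal-codon set from noise alone;
emptiness would require libraries roughly an order of magnitude deeper. The
acceptance suite states the emptiness expectation at plastome scale and the
corresponding test fails honestly; treat small-library optimal-codon lists
as hypotheses, not detections.

## Numerical choices and degenerate inputs

- Frame errors (length not divisible by 3) abort counting with the gene
  named; ambiguity-containing triplets are skipped and reported.
- `0 · log 0 = 0` in entropies; `mean()` over an empty usable-family class
  is the trigger for ENC imputation/undefinedness, never `NaN` leakage.
- ENC capped into [20, 61]; SCUO, PR2 coordinates bounded in [0, 1] by
  construction; `milc = 1 − cai` is exact, not recomputed.
- All-equal ranking metrics produce id-ordered tails with a warning;
  identical taxa cluster at height 0; non-finite distances name the pair.
- Every stochastic step takes an explicit integer seed; the generator
  restores the caller's RNG state.

## Known limitations

- CAI (hence the expression proxy and the libraries) depends on the
  reference choice; without expression data the self-referential default is
  reproducible but not biologically validated.
- The GenBank reader handles the feature syntax seen in plastome records
  (`complement`, `join`, nesting, partial markers); it is not a full
  flat-file grammar and skips what it cannot resolve, with warnings.
- RSCU vectors admit no likelihood, so taxon clustering is hierarchical
  (UPGMA on Euclidean distance by default, correlation distance and other
  linkages as options), and branch lengths are merge heights, not
  evolutionary distances.
- Codon-pair bias, dinucleotide effects, tRNA adaptation and
  correspondence analysis are out of scope.
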