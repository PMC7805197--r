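---
title: "Directional drug-signature enrichment: model, null, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional drug-signature enrichment: model, null, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpgsea)
```

## The screening model

`dpgsea` asks, for each drug in a proto-matrix, whether the genes that drug
regulates — in the direction it regulates them — are concentrated among the
most significant genes of a disease DE contrast. Two inputs define a screen:

* a **DE table**: per gene, a signed effect (log2 fold-change or signed
  moderated statistic) and a significance value in (0, 1];
* a **proto-matrix**: per drug (typically drug + cell line), its top-N
  perturbation-responsive genes, each with the direction (+1/−1) the drug
  drives it. This is richer than a plain gene set: membership alone is not
  enough, the drug-gene direction must also oppose (antagonist mode, the
  signature-reversion use case) or match (agonist mode, validation against
  the drug's own perturbation data) the disease direction for a gene to
  count as a hit.

The ranked list L orders genes by |T| descending, where the ranking
statistic is T(j) = −log10(significance) carrying the sign of the effect
(a signed-statistic alternative is available via `rank_stat_kind`).
Ranking by significance rather than fold-change lets the method exploit the
full inferential output of the upstream DE model. Ties in |T| break by
lexicographic gene identifier so all outputs are reproducible.

### Running sum and scores

With hit indicator I[σ(j) ∈ S_k] over ranks j = 1..p and γ_k hits, the
weighted running sum is

$$v_k(l) = \frac{\sum_{j \le l} |T_{(j)}|^{\omega}\, I[\sigma(j) \in S_k]}
               {\sum_{j=1}^{p} |T_{(j)}|^{\omega}\, I[\sigma(j) \in S_k]}
         - \frac{\sum_{j \le l} I[\sigma(j) \notin S_k]}{p - \gamma_k},$$

so v(p) = 0 exactly and ES_k = max_l |v_k(l)| lies in [0, 1]. The score is
an absolute maximum deviation: enrichment is reported on a one-sided
positive scale, and when the extreme deviation is negative (hits depleted
from the head of the list) the driver genes are taken as the hits *after*
the peak, the usual GSEA convention; otherwise they are the hits at ranks
≤ l̂max. This keeps the driver set non-empty whenever γ ≥ 1.

The target compatibility score measures where enrichment peaks rather than
how high the sum gets: TCS_k = |l̂max − l̂min|, with l̂min the rank of
minimal |T| — under the descending sort, the bottom of the list (first such
rank on ties; argmax ties likewise resolve to the smallest rank, so both
indices are deterministic). We report TCS scaled to [0, 1] by (p − 1), which
maps maximal separation — a peak at rank 1 — to exactly 1 and matches the
magnitudes practitioners expect for top-ranked enrichments (values like
0.98–0.999). Scaling by p or by l̂min would compress the same information;
(p − 1) is the choice that makes the extremes exact.

### Parameters that matter

* `omega` (default 1): the running-sum weight exponent on |T|. At 0 the
  statistic reduces to the classic unweighted Kolmogorov–Smirnov-style set
  statistic; at 1 — the GSEA-classic choice this method mirrors — each gene
  contributes proportionally to its evidence. Values above 1 let a handful
  of extreme genes dominate; we default to 1 and expose the knob.
* `mode` (default `"antagonist"`): signature reversion is the screening use
  case; `"agonist"` finds positively correlated perturbations. Flipping
  every signature direction and switching mode yields byte-identical
  reports — the two modes are the same computation under relabeling.
* `n_perm` (default 1000): permutations per drug. Empirical p-value
  resolution is 1/n_perm; fewer than 100 triggers a warning.
* `top_n` in the builder ({10, 20, 50} are conventional): signature size.
  Smaller signatures favor TCS-style detection; larger ones give ES more
  genes to integrate over. Signatures built at smaller N are prefixes of
  those built at larger N under the same ranking.

## Permutation null, normalization, and error rate

For each drug the gene labels of L are permuted while the rank-ordering
(hence the weight vector) stays fixed — equivalently, the γ hit positions
are redrawn uniformly without replacement — and both scores are recomputed.
This single per-drug ensemble serves three purposes: the normalization
factor (NES = ES / mean null ES, likewise NTCS), the empirical p-value, and
the pooled FDR.

The p-value is the proportion of permuted scores *strictly greater* than
the observed score, stored as r/n_perm: r = 0 is representable and rendered
as `< 1/n_perm` in printed output. No +1 smoothing is applied — the
rendering floor makes the resolution explicit instead.

FDR follows the GSEA pooled-null construction: each drug's null scores are
normalized by that drug's null mean (necessary for cross-drug
comparability), pooled across all screened drugs, and the q-value for a
drug with normalized score s is the fraction of pooled nulls ≥ s divided by
the fraction of observed normalized scores ≥ s, clipped to [0, 1]. A
monotone step-up pass (each drug takes the minimum raw q among drugs with
scores no larger than its own) makes reported q non-increasing in score,
the convention users expect when thresholding. p-values are computed on raw
scores (per-drug nulls make this scale-invariant); FDR on normalized
scores. Benjamini–Hochberg adjustment of the empirical p-values is *not*
the primary error rate — the pooled permutation FDR is better matched to
exploratory drug screening — but `stats::p.adjust` can of course be applied
to the report's p-value columns by users who want it.

Permutation streams are seeded per drug from a hash of (master seed,
drug id), so a drug's statistics do not depend on screening order or on
which other drugs share the proto-matrix, and a fixed (inputs, seed,
n_perm) triple reproduces the report byte for byte.

### Numerical notes

The permutation loop evaluates the running-sum extrema in O(γ) per draw
from the hit positions alone: between hits v is linear with slope
−1/(p − γ), so max |v| occurs at a hit rank, the rank just before a hit, or
at p. The cumulative sums are arranged so this fast path produces floats
identical to the full O(p) path used for observed scores; a test asserts
exact agreement. Degenerate inputs are handled explicitly: γ = 0 drugs get
NA rows (with `n_hits = 0`) rather than being dropped; γ = p returns the
hit fraction alone with a warning; all-zero hit weights (every hit at
significance 1) fall back to the unweighted hit fraction; significance
values of 0 from upstream underflow are clamped to 1e−300 so logs stay
defined; duplicate genes keep the most significant row (the conservative
choice for a significance-ranked method — averaging duplicates would
manufacture evidence neither row contains). Genes with
effect exactly 0 carry no direction, so they can never be directional hits,
and the proto-matrix builder excludes them from signature candidacy with a
warning.

## What the synthetic generator emulates — and what it does not

`simulate_screen_inputs()` generates screens at the level the method
consumes: a DE table whose background genes have uniform(0, 1)
significances and standard-normal effects, plus drug signatures. Spiked
drugs receive `signature_size` genes of which a fraction `concordance` are
made antagonist-compatible (disease sign set opposite the drug direction)
with significances 10^−(Exp(mean = spike_strength) + 1) — an exponential
tail on the −log10 scale, so spiked genes concentrate near the top of the
ranked list at stochastic positions, the way true perturbation targets
surface in a real DE experiment. Null drugs draw signatures uniformly.
Defaults (2000 genes, signature size 20, concordance 1, spike strength 3)
are the conditions under which the package's power and calibration
properties are stated.

The generator does not simulate read counts, library-size or batch
effects, gene-gene correlation, or the upstream DE model — backgrounds are
exchangeable by construction. Passing calibration tests therefore shows the
permutation machinery is correct under its own null, not that real DE
tables (where correlated gene modules violate label exchangeability) will
have exactly nominal error rates; that caveat is inherited from all
gene-label permutation methods, this one included.

## Problem sizes used by the test suite

The statistical tests run at deliberately desk-sized conditions: 1000
random instances (p ≤ 50, γ ≤ 10) against a literal double-loop oracle;
exhaustive enumeration at p = 10, γ = 2 versus 20,000 permutations; 500
single-drug null screens of 1000 genes at 1000 permutations for type-I
error; 100 seeds of a 10-drug, 2000-gene spiked screen for power; and 20
fifteen-drug screens with weak spikes for the TCS/driver-set-size trend.
These sizes give binomial/KS standard errors comfortably inside the
asserted bands while keeping the whole suite in a few minutes.

## Known limitations

* Significance-tied inputs (many identical p-values) make ranking
  tie-dominated; the package warns and falls back to lexicographic order,
  but the scores then carry little information.
* TCS is defined relative to the bottom of the ranked list; for very small
  p its (p − 1) scaling is coarse.
* The pooled FDR assumes enough drugs for the observed-score denominator to
  be meaningful; a one-drug screen's q-value is effectively its p-value
  rescaled.
* Proto-matrix quality bounds everything: signatures derived from a cell
  line far from the disease tissue can be directionally wrong in ways no
  statistic detects.
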