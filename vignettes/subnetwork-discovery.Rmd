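---
title: "Phenotype-specific pathway subnetwork discovery: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-specific pathway subnetwork discovery: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SNet)
```

## The problem

Single-gene differential-expression tests are notoriously irreproducible
across independent cohorts of the same disease: two labs profiling the same
condition on different platforms typically agree on only a minority of their
top genes. This package implements a subnetwork-level alternative. Instead
of asking which genes are differentially expressed, it asks which *connected
portions of curated pathways* are consistently highly expressed in one
phenotype. Requiring cross-patient consistency *and* connectivity in a
gene–gene relationship graph discards the sporadic, solitary hits that drive
irreproducibility, and returns results (subnetworks) that describe the
interplay of the affected genes rather than a flat list.

## The procedure

Let the phenotype of interest be $d$ with $n$ patients $P_1,\dots,P_n$, and
pool the remaining patients $P_{n+1},\dots,P_m$ as $\neg d$. A pathway
database supplies named pathways, each a set of undirected gene–gene edges
typed as activation or inhibition.

**1. Candidate genes and subnetworks.** For each patient, rank all genes by
expression within that patient and keep the top $\alpha\%$ (set
$G_{P_i}$). Keep genes appearing in $G_{P_i}$ for *strictly more than*
$\beta\%$ of the phenotype-$d$ patients (list $GL$). Within each pathway
independently, restrict the pathway graph to edges whose both endpoints lie
in $GL$ and take every connected component with at least `minSize` genes as
a candidate subnetwork. Genes of $GL$ left with no edge in a pathway are
solitary there and are dropped. A gene may appear in subnetworks of several
pathways.

**2. Scoring.** For subnetwork $sp$ and *every* patient $P_i$ (regardless of
phenotype), the score is

$$S_{sp}(P_i) \;=\; \sum_{g \in sp \,\cap\, G_{P_i}} \frac{k_g}{n},$$

where $k_g$ is the number of phenotype-$d$ patients with $g$ in their
top-$\alpha$ set. The score lies in $[0, |sp|]$ and rewards genes that are
both highly expressed in this patient and consistently highly expressed
across the $d$ group. Splitting the scores into the $d$ group and the rest
gives two score vectors, compared with a Welch $t$-statistic.

**3. Significance.** Phenotype labels are randomly permuted across all
samples (group sizes preserved); steps 1–2 are rerun in full for every
phenotype; each re-extracted subnetwork contributes one (size, $t$) pair to
a pooled two-dimensional null. The p-value of an observed subnetwork of size
$s$ and statistic $t$ is

$$p = \frac{1 + \#\{\text{null entries with size} \ge s,\ |t_e| \ge |t|\}}
          {1 + \#\{\text{null entries with size} \ge s\}},$$

and subnetworks with $p \le$ `pCutoff` (inclusive) are reported. Every
phenotype is taken as $d$ in turn; duplicate discoveries (same pathway, same
gene set) keep the occurrence with the larger $|t|$.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 10 (%) | per-patient top-rank cut; `ceiling(alpha/100 * G)` genes |
| `beta` | 50 (%) | cross-patient frequency threshold, strict `>` |
| `nPerm` | 1000 | label permutations pooled into the null |
| `pCutoff` | 0.05 | significance threshold, inclusive |
| `minSize` | 5 | smallest reported subnetwork (genes) |
| `sizeBin` | `"tail"` | null conditioning: `size >= s` or exact size |

The `alpha = 10`, `beta = 50`, `nPerm = 1000`, `pCutoff = 0.05` operating
point is the method's published one. `minSize = 5` reflects the observation
that meaningful discoveries at this operating point always carried at least
five genes; it is configurable.

## Numerical and design choices

**Per-patient score.** The score is the sum of $k_g/n$ over the patient's
highly expressed subnetwork genes — the only form consistent with the
stated meanings of $g$, $k$ and $n$. Each term lies in $(0, 1]$, so the
score is bounded by the subnetwork size, and a patient scores high exactly
when the genes it shares with the subnetwork are the ones the $d$ group
agrees on.

**Ties and determinism.** The top-$\alpha$ cut breaks boundary ties by gene
identifier (ascending, C collation); duplicate expression rows collapse to
the highest-mean row; subnetwork hubs (used in names,
`<phenotype>_<pathway>_<hub>`) are the maximum-degree gene with
lexicographic tie-break. Identical inputs and seed give byte-identical
result files.

**Welch statistic and degenerate vectors.** The published description says
only "t-statistics"; this implementation uses the unequal-variance (Welch)
form, since the two score groups have no reason to share a variance. When
both score vectors are constant, the statistic is defined as 0 for equal
means and a signed sentinel ($\pm 10^9$) otherwise, so perfectly separated
degenerate subnetworks sort above any finite statistic rather than failing.

**Null conditioning.** Exact-size bins are routinely empty at a thousand
permutations, so the default conditions on the right size tail
(size $\ge s$) with an add-one pseudocount; larger random subnetworks with
equal $|t|$ are rarer, so pooling them is conservative. Exact binning is
available via `sizeBin = "exact"`. A consequence of the tail-plus-pseudocount
form is a p-value floor of $1/(1+|E|)$: an observed subnetwork larger than
anything the null ever re-forms gets $p = 1$. This is deliberate
conservatism — without null subnetworks of comparable size there is no
evidence scale — but it means `nPerm` must be large enough for the null to
populate the relevant sizes.

**Selection offset of the null.** Permuted-label $t$ statistics are not
centred exactly at zero: the frequency filter selects genes frequent in the
permuted $d$ group, tilting the score contrast positive (about $+0.9$ at a
permissive operating point, roughly one null standard deviation). The
offset is intrinsic to re-running the selection inside the permutation —
which is precisely what makes the null valid: observed and permuted
statistics pass through the same selection, and the empirical false-positive
rate on exchangeable data sits at the nominal level (see below).

**Edge signs.** Activation/inhibition annotations are carried through to
the SIF output but play no computational role: extraction and scoring use
the edges purely for connectivity.

**No multiplicity correction.** Significance is the nominal $p \le 0.05$
against the permutation null, faithful to the method as published; the
output table carries all p-values so users may apply their own correction.

## What the synthetic data emulates

The generator (`simConfig`, `generatePathwayDB`, `generateCohort`,
`generatePlatformPair`) produces connected random pathway graphs (random
spanning tree plus extra edges), i.i.d. Gaussian log-scale expression with
per-gene baseline Normal(8, 1) — a typical log2 microarray intensity range —
and planted connected components shifted upward by `effectSize` baseline
standard deviations in the case group. Pathway-free background genes keep
the top-percentile cut from being dominated by pathway genes. Platform
pairs share the database and plants but draw fresh samples and noise and
independently drop a fraction of non-planted genes, emulating probe-coverage
differences between arrays.

This emulates what the method needs to be tested against — rank structure,
cross-patient consistency, connectivity, platform disjointness — and
deliberately not what it does not: no probe-level error model, no
batch effects, no correlated co-expression outside the planted components,
no heavy-tailed noise. Passing tests on these fixtures demonstrate the
algorithmic properties (calibration, recovery, cross-dataset stability
relative to a per-gene baseline), not performance on any real disease
cohort.

## Preset study conditions

Three presets (`snetPreset`) fix the conditions used by the test suite and
the reproduction script:

* **null** — effect 0, 20 pathways, 15+15 patients. Used to check that the
  fraction of subnetworks reaching $p \le 0.05$ on exchangeable data is
  about 5%. With the default filter nothing survives on unstructured data
  (the probability of a null gene passing `beta = 50` at $\alpha = 10\%$,
  $n = 15$ is about $10^{-5}$) — that is the method's false-positive
  defence, but it leaves nothing to calibrate on — so this preset bundles a
  permissive filter (`alpha = 30`, `beta = 30`).
* **planted-small** — one 8-gene planted component at effect 3, default
  filter, 200 permutations. At effect 3 a planted gene lands in a case's
  top decile with probability $\approx \Phi(3 - 1.28) \approx 0.96$, so the
  plant is recovered essentially always; recovery is measured as a
  significant subnetwork in the planted pathway with gene-set Jaccard
  $\ge 0.8$ against the manifest.
* **platform-pair** — three 8-gene plants at effect 2.3, 10+10 patients,
  2000 background genes, 10% gene dropout, 1000 permutations. Chosen by
  power analysis as the regime that separates the two philosophies: the
  per-gene Welch $t$ of a planted gene ($\approx 5.1$, noise sd
  $\approx 1.3$) straddles the maximum null $t$ over ~2400 genes
  ($\approx 3.9$), so top-$\gamma$ t-test lists churn between platforms,
  while each planted gene passes the rank-frequency filter with
  probability $\approx 0.99$ and the connectivity requirement removes null
  intruders, keeping subnetwork gene lists stable. The 1000 permutations
  keep the p-value floor (above) near 0.02, comfortably under the cutoff.
  At effect 3 both approaches recover the plants perfectly and the
  comparison degenerates to a tie; at effect $\lesssim 1.8$ the permuted
  null no longer re-forms full-size components and the size-tail p-value
  cannot reach the cutoff at all.

Replicate counts in the test suite (50 calibration seeds, 40 recovery
seeds, 25 platform pairs) and the reproduction script (20/20/12) are the
package's chosen problem sizes: large enough for the binomial/median
comparisons involved, small enough to rerun casually.

## Known limitations

* Only *up*-regulation within a phenotype is detected directly;
  down-regulation in $d$ surfaces as up-regulation when another phenotype
  plays the role of $d$, which requires that the other phenotype is
  genuinely higher there, not merely less low.
* Gene identifiers are matched as exact case-sensitive strings between the
  expression matrix and the pathway database; identifier harmonisation is
  the user's responsibility.
* The permutation null pools all pathways; a pathway with unusual topology
  (say, one giant hub) is judged against the global size–score null, not a
  pathway-specific one.
* With very small cohorts the frequency filter quantises coarsely (at
  $n = 4$, `beta = 50` means "3 or more patients"), and the permutation
  space itself is small; p-values are then lumpy.
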