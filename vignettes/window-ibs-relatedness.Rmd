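---
title: "Relatedness from windowed identity-by-state: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness from windowed identity-by-state: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Two people who share a recent common ancestor share long chromosomal
segments identical by descent (IBD). Genome-wide averages of allele sharing
(identity by state, IBS) blur this signal: as relationships become more
distant, the variance of a genome-wide mean overwhelms the shrinking
difference in its expectation, and per-site sequencing noise adds to it.
`kinwin` instead works at the scale where the signal lives — the segment —
while averaging noise away below that scale. It is a low-pass filter over
the genome:

1. The autosomes are tiled with non-overlapping windows of 1 Mb (the
   whole-genome-sequencing setting) or 2 Mb (for sparser genotyping-array
   densities). Windows are half-open on 1-based coordinates; a site at
   position $p$ belongs to window $\lfloor (p-1)/w \rfloor$.
2. Within each window, every site fully called in both individuals is
   classed IBS2 (identical genotypes), IBS1 (one shared allele) or IBS0 (no
   shared allele), and the window is summarised by the fractions
   $P_0, P_1, P_2$ (with $P_0 + P_1 + P_2 = 1$).
3. A window with $P_0$ below an error-dependent cutoff is an **identity
   window** (IW): at least one haplotype is effectively shared across it,
   because true IBS0 sites are impossible where one haplotype is shared, so
   any residual $P_0$ must come from genotyping error.
4. Five pair-level statistics feed a small classification tree:
   the number of windows with $P_2 \in (0.8, 1]$ and a flag for whether the
   high-$P_2$ histogram peak dominates (both driven by IBD2, the
   full-sibling signature); and the count, contiguous percentage and longest
   run of IWs (driven by IBD1 sharing, which decays geometrically with
   relationship degree).

The tree emits `IT` (identical twin / same sample), `FS`, `PO`,
`D2`–`D5` (2nd- to 5th-degree), `UD` (related, degree not determined) or
`UN` (unrelated). Parent–offspring pairs share one haplotype everywhere, so
their IW fraction is ~1; each additional degree roughly halves the shared
fraction, which is why a ladder of decreasing cuts on the IW fraction
separates the degrees. Beyond 5th degree, the IW count falls into the noise
floor and only contiguity evidence (adjacent IWs, long runs) distinguishes
a distant relative from an unrelated pair — hence `UD` versus `UN`.

No phasing, no population allele frequencies and no genetic map are
required; this is deliberate, and it is what makes the method usable on
sparsely studied populations.

## The error model and the $P_0$ cutoff schedule

`se` is the per-genotype error rate: the probability that a called genotype
is wrong. For a window truly sharing a haplotype, errors convert a small
fraction of sites into apparent IBS0, so the IW rule $P_0 < \text{cutoff}$
must budget for them. The shipped schedule pins cutoffs
$(0, 0.004, 0.01, 0.015)$ at $se = (0, 0.001, 0.005, 0.01)$, interpolating
linearly between these anchors and extending proportionally ($1.5\,se$)
above the last one; it is non-decreasing in `se`.

Two numerical choices deserve a note:

* **The error-free boundary.** The rule is strict (`P0 < cutoff`), but at
  `se = 0` the cutoff is 0 and a strict comparison would reject even
  perfect windows. Error-free shared windows have exactly zero IBS0 sites,
  so the `cutoff = 0` case is special-cased to `P0 == 0`.
* **The anchor band.** The anchors bracket, but do not all lie inside, the
  band $[1-(1-se)^2,\, 1-(1-se)^4]$ that motivates them (at $se = 0.01$ the
  anchor 0.015 sits below $1-(1-se)^2 \approx 0.0199$). We keep the anchors
  verbatim and keep the schedule monotone rather than forcing band
  containment; the three properties cannot hold simultaneously.

## Calibration

Numeric thresholds are not fixed a priori; they are learned, exactly as the
method was originally trained, from one simulated family with known truth
(`calibrate_thresholds()`). Every decision boundary is a one-dimensional
cut chosen to maximise exact-label accuracy between the two classes it
separates, with ties broken toward the midpoint of the gap between the
class-conditional ranges — deterministic given the training data. The
packaged defaults (`default_thresholds()`) come from one 26-member
training family simulated at 600k sites, SE = 0, seed 1, and are stored as
a flat key-value text config.

Two tree details were genuinely open and were settled as follows:

* **Sibling node.** Both IBD2 statistics are computed, but either suffices
  for an `FS` call: the peak-dominance flag loses sensitivity as genotyping
  error smears the IBD2 spike away from $P_2 = 1$ (at `se = 0.01` about one
  sibling pair in ten loses the peak), while the high-$P_2$ window count
  keeps a several-fold margin over every non-sibling class at every error
  rate in the schedule, and both signals are near-perfectly specific. The
  OR keeps first-degree accuracy flat across the error schedule.
* **Peak histogram bins.** The peak comparison uses bin width 0.01 on
  $P_2 \in (0,1]$. With synthetic independent-site founders the window
  $P_2$ values are tightly concentrated (sd ≈ 0.03 at ~200 sites/window);
  wider bins let the broad IBD1 mass (half the genome for a sibling pair)
  out-peak the IBD2 spike (a quarter of the genome, but at exactly
  $P_2 = 1$ when error-free). Narrow bins preserve the spike's dominance,
  which is the intent of the statistic.

Other defaults: the twin gate requires high-$P_2$ coverage of more than
0.95 of windows (self/twin pairs sit at 1 by construction); windows with
fewer than 10 co-called sites (5 in array mode) are dropped before any
metric is computed; no call is attempted from fewer than 100 retained
windows; the contiguous-IW percentage is normalised by the IW count (not
the window count); and IW adjacency never crosses a chromosome boundary,
because there is no meiotic linkage across chromosomes.

## The simulator

`make_site_map()`, `simulate_founders()`, `gene_drop()` and `apply_error()`
emulate a WGS-scale biallelic SNV callset for an arbitrary pedigree:

* **Sites.** Positions uniform over GRCh37 autosome lengths (3.5 million
  genome-wide by default, the scale of a human WGS callset); alternate
  allele frequencies drawn from a Beta(0.5, 0.5) spectrum (U-shaped,
  enriched for rare and near-fixed alleles; configurable).
* **Founders.** Haplotype alleles drawn independently per site as
  Bernoulli(frequency). These synthetic founders replace real sequenced
  genomes, which cannot be redistributed.
* **Meiosis.** Crossovers per chromosome are Poisson(length × rate) with
  uniform breakpoints and no interference, at 1 cM/Mb (1e-8 per bp) — a
  uniform genetic map.
* **Error.** With probability `se` per genotype per individual, the call is
  replaced by one of the two other codes, uniformly.

What this emulates well: segment-scale IBD structure, Mendelian
transmission, the density of a WGS callset, and a tunable error rate. What
it does not emulate: linkage disequilibrium and local site clustering, a
realistic human site-frequency spectrum, recombination hotspots and
interference, and caller-specific error structure (depth- and
context-dependent errors, half-calls). Consequently the close-relationship
results transfer well, while deep-degree accuracies are reproduced only
approximately: independent-site founders make sparse IBD segments *cleaner*
than in real data, so 6th/7th-degree detection rates here run somewhat above
the rates reported for CGI-founder simulations.

The packaged 26-member, 7-generation pedigree (`default_pedigree()`,
`inst/extdata/pedigree_7gen.ped`, synthetic) was constructed so that a
single family contains every class the tree must learn: 8 sibling pairs, 32
parent–offspring pairs, 42 second-degree pairs, third- through fifth-degree
pairs, 6th- to 9th-degree pairs (labelled `UD`) and 141 unrelated pairs
(founders and married-in lines). Truth labels come from the recursive
kinship matrix: degree $= -\log_2(2\varphi)$ rounded, with PO/FS resolved
structurally and $\varphi = 0$ mapped to `UN`.

## Problem sizes and reproducibility

The validation experiment (`relatedness_experiment()`, also behind
`scripts/acceptance.R` and the acceptance tests) uses 5 replicate families
on a shared 600k-site map — dense enough that every 1 Mb window holds ~200
sites and the noise floor for unrelated pairs is effectively zero, while a
full calibrate-and-evaluate cycle over three error rates completes in a few
minutes on one CPU. Replicates share one site map so that founders of
different replicates can be paired as known-unrelated individuals over
common sites. All randomness flows from a single integer seed.

At these settings the held-out accuracies are: full siblings,
parent–offspring and unrelated pairs exact at every error rate in the
schedule (0, 0.001, 0.01 with matched cutoffs); second-degree ≈ 0.97;
third-degree ≈ 0.89; accuracy decaying through the fifth degree with
within-one-degree accuracy ≈ 1; and most 6th/7th-degree pairs detected as
related (not by degree) at `se = 0.001`. These are the quantities the test
suite asserts; nothing beyond them is claimed.

## Known limitations

* Degree estimates beyond the 5th are intentionally out of scope; the tree
  stops at `UD`/`UN`. Likelihood methods over explicit IBD segments are the
  right tool there.
* Window statistics assume autosomal diploid inheritance; sex chromosomes
  are excluded by default.
* The PED/MAP dialect without allele columns cannot distinguish REF from
  ALT; the first allele observed at a site is taken as provisional REF,
  which is irrelevant to IBS but flips the exported coding at such sites.
* Calibration needs every class present in the training family; with
  sparse maps (few hundred windows) adjacent deep-degree classes overlap
  and the fitted ladder is repaired to stay strictly decreasing, with a
  warning.
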