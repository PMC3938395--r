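# kinwin

Relatedness inference from whole-genome variant calls, for people running
family-based genome studies, cohort QC, or forensic/genealogical analyses:
given multi-sample genotypes, `kinwin` tells you, for any pair of
individuals, whether they are the same sample / identical twins (`IT`),
full siblings (`FS`), parent–offspring (`PO`), 2nd- through 5th-degree
relatives (`D2`–`D5`), related at an undetermined distance (`UD`), or
unrelated (`UN`). Typical uses: validating reported pedigrees, catching
sample swaps and duplicate inclusions, and screening cohorts for cryptic
relatedness — without phasing and without population allele-frequency
panels.

## Method

The genome is segmented into non-overlapping windows (1 Mb for WGS, 2 Mb
for array densities). Within each window, every site fully called in both
individuals is classed by identity by state — IBS2 (identical genotypes),
IBS1 (one shared allele), IBS0 (none) — giving window fractions
P0, P1, P2. A window whose P0 falls below a sequencing-error-dependent
cutoff is an *identity window* (IW): shared-haplotype windows can show
IBS0 only through genotyping error, so the cutoff schedule follows the
error rate SE, with cutoffs (0, 0.004, 0.01, 0.015) at
SE = (0, 0.001, 0.005, 0.01).

A classification tree over five pair statistics then emits the call:

* `n_high_p2`, the number of windows with P2 ∈ (0.8, 1], and `peak_flag`,
  whether the P2 histogram peaks in that region — IBD2 signals that
  identify twin/self and full-sibling pairs;
* `n_iw`, the IW count: ≈ all windows for parent–offspring, roughly
  halving per additional degree;
* `frac_contig_iw` and `max_run`, contiguity of IWs within chromosomes,
  which separate distant-but-real relatives (`UD`) from unrelated pairs.

Thresholds are not hard-coded: they are calibrated
(`calibrate_thresholds()`) on a simulated family with known truth, using
the packaged gene-dropping simulator (synthetic Beta-spectrum founders,
Poisson recombination at 1 cM/Mb, per-genotype error injection). Packaged
defaults live in `inst/extdata/default_thresholds.tsv`.

Input formats: VCF 4.x (plain or gzip), PLINK PED+MAP and TPED. Only
biallelic autosomal SNVs with full calls in the pair are used.

## Worked example

Simulate a small five-chromosome family from the packaged 26-member
pedigree, inject a 0.1% genotyping error, and classify a few pairs:

```r
library(kinwin)

lengths <- c(`1` = 80e6, `2` = 70e6, `3` = 60e6, `4` = 50e6, `5` = 40e6)
sites   <- make_site_map(n_sites = 80000, chrom_lengths = lengths, seed = 1)
family  <- simulate_family(default_pedigree(), sites,
                           chrom_lengths = lengths, seed = 2)
gm      <- apply_error(family, se = 0.001, seed = 3)
gm
#> <genotype_matrix> 80000 sites x 26 samples (chrom 1,2,3,4,5)
#>   samples: A1, A2, C1, C2, E1, E2, G1, G2
#>   missing calls: 0.000%

calls <- relate_pairs(
  gm,
  pairs = rbind(c("A1", "B1"), c("B1", "B2"), c("A1", "D3"), c("A1", "A2")),
  chrom_lengths = lengths, se = 0.001, min_windows = 50
)
dplyr::select(calls, sample1, sample2, n_iw, n_windows, n_high_p2, label, degree)
#> # A tibble: 4 × 7
#>   sample1 sample2  n_iw n_windows n_high_p2 label degree
#>   <chr>   <chr>   <int>     <int>     <int> <fct>  <int>
#> 1 A1      B1        286       300         4 PO         1
#> 2 B1      B2        219       300        71 FS         1
#> 3 A1      D3        171       300         2 D2         2
#> 4 A1      A2          0       300         0 UN        NA
```

Reading the rows: `A1–B1` is a parent–offspring pair — nearly every window
is an identity window (286/300) but almost none reach P2 > 0.8, because
exactly one haplotype is shared everywhere. `B1–B2` are full siblings:
fewer IWs, but 71 windows with near-total genotype identity (IBD2 tracts).
`A1–D3` (grandparent–grandchild) shares about half the genome, and the
unrelated founder pair `A1–A2` shares nothing. `degree` is the numeric
degree of the call (0 for `IT`, 1 for `FS`/`PO`, …, `NA` for `UD`/`UN`).

On real data, start from `read_genotypes("cohort.vcf", format = "vcf")` or
use the command-line wrapper installed at `exec/kinwin`
(`kinwin estimate --input cohort.vcf --out calls.tsv --se 0.001`). Each
result row is written by `write_calls()` as a TSV with the five statistics
and the predicted label.

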