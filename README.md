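# scnaclone

Somatic copy-number aberration (SCNA) calling from paired tumor–normal
sequencing data, with explicit estimation of tumor purity and subclonality.

## Who this is for

Cancer genomics analysts with whole-genome (or dense targeted) sequencing
of a tumor and its matched normal who need, beyond segment calls: the
fraction of admixed normal cells in the tumor sample, absolute per-segment
allelic copy numbers, and — for one-copy events — the fraction of tumor
cells that carry each aberration.  Input is a per-SNP table of read depths
(RD) and lesser-allele frequencies (LAF = min(BAF, 1−BAF)); a pair of VCFs
with `DP`/`AD` fields can be ingested directly.

## The model in brief

* **Segmentation.** Heterozygous-site LAF is outlier-smoothed, then change
  points are over-detected by circular binary segmentation (run on the
  sequence padded with pseudo points at the chromosome ends as a variance
  control) and pruned by stepwise selection with a BIC on the piecewise-
  constant model (penalty `k·log n·log log n`).
* **Somatic ratio.** Per segment, the tumor/normal depth ratio `r` is the
  MLE under the Geary–Hinkley transform `z_i(r) = (r·y_i − x_i)/√(r²y_i + x_i)`
  of the paired (Poisson-approximated) depths; adjacent segments with
  `|Δr| < 0.05` are merged and re-estimated to a fixed point.
* **Admixture rate.** Somatic copy levels `s = 2r` of clonal segments sit
  on the lattice `2α + (1−α)c`, anchored at ratio 1 ↔ copy 2 (no ploidy
  search).  A finite Gaussian mixture (AIC-selected K, MCMC allocation with
  component variance 0.01, Dirichlet prior on weights) assigns integer copy
  states; ambiguous segments are candidate subclonal and excluded; then
  `α̂ = Σw(2−c)(s−c) / Σw(2−c)²`, capped at 0.8.
* **Subclonality.** Each aberrant segment is tested against a clonal
  change of exactly one allele copy: null ratio `(nA+nB±1)/(nA+nB)` with a
  bootstrap SD; rejection with implied fraction inside (0,1) yields a
  subclonal call with `f = (2r_adj − (nA+nB)) / ((nA_t+nB_t) − (nA+nB))`.
  Multi-copy subclones are not quantified — a 5-copy gain in 30% of cancer
  cells, 4 copies in 45% and 3 copies in 90% all produce adjusted ratio
  1.45 and cannot be distinguished from the ratio alone.

A simulator implementing the 7-step evaluation protocol (template normal
genome, 10 kb window statistics, event placement, admixture blending,
coverage thinning) plus a scoring harness ship as first-class modules; see
the methods vignette (`vignettes/scna-calling-methods.Rmd`) for the full
model description, parameter table and limitations.

## Worked example

Simulate a 3-chromosome tumor–normal pair at 40% normal contamination with
a clonal LOH, a clonal double deletion, a clonal 1-copy gain and a
subclonal 1-copy gain in 40% of the cancer cells, then call it:

```r
library(scnaclone)

ev <- data.frame(
  chrom = c("chrA", "chrA", "chrB", "chrC"),
  start = c(4e5, 2.2e6, 1e6, 5e5),
  end   = c(1.2e6, 2.9e6, 2.4e6, 1.6e6),
  type  = c("LOH", "double_deletion", "gain1", "gain1"),
  subclonal_fraction = c(1, 1, 0.4, 1))
cfg <- sim_config(chrom_lengths = c(chrA = 3e6, chrB = 3e6, chrC = 3e6),
                  admixture_rate = 0.4, seed = 42)
sim <- simulate_genome(cfg, ev)       # 9,900 paired SNPs
res <- run_pipeline(sim$snps, scna_config(seed = 1))
print(res)
#> SCNA calling result
#>   admixture rate: 0.438
#>   mixture components: 5 at levels 0.92, 1.40, 2.00, 2.31, 2.59
#>   segments: 12 on 3 chromosome(s); aberration events: 6
#>   events by type: gain=4, LOH=1, loss=1
#>   subclonal events: 2
```

The admixture rate is recovered as 0.438 (truth 0.4).  The event table
(`res$events`) reads:

```
 chrom   start     end ratio r_adj copies     class    f event
  chrA  400010 1200942 0.699  0.46    1+0    clonal 1.00   LOH
  chrA 2196949 2978193 0.461  0.04    0+0    clonal 1.00  loss
  chrB  996476 2400710 1.119  1.21    2+1 subclonal 0.42  gain
  chrC  500235 1090685 1.306  1.55    2+1    clonal 1.00  gain
  chrC 1090685 1099316 1.187  1.33    2+1 subclonal 0.67  gain
  chrC 1099316 1597244 1.285  1.51    2+1    clonal 1.00  gain
```

Reading it: the LOH segment has raw ratio 0.699 ≈ the expected
`(2·0.4 + 0.6·1)/2 = 0.7`, adjusted ratio 0.46 ≈ one remaining copy, tumor
allelic copies 1+0; the double deletion adjusts to ≈ 0 copies and is
labeled a clonal loss; the chrB gain is correctly quantified as subclonal
with `f = 0.42` (truth 0.40); the chrC clonal gain is called at adjusted
ratio ≈ 1.5 (copies 2+1).  The 9 kb sliver inside chrC flagged subclonal
is an over-segmentation artifact of the kind the scoring harness counts as
a false positive — at realistic genome sizes these are rare (precision
0.9–1.0 on the simulation grids).

From the shell, the same pipeline runs as

```sh
Rscript inst/cli/scna.R simulate --alpha 0.4 --coverage 40 --seed 7 --out sim/
Rscript inst/cli/scna.R run --input sim/rep1_snps.tsv --out calls/
```

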