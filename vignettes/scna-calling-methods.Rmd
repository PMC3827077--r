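---
title: "Calling somatic copy-number aberrations with purity and subclonality estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic copy-number aberrations with purity and subclonality estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnaclone)
```

## The problem

Whole-genome sequencing of a tumor together with a matched normal sample
makes it possible to call somatic copy-number aberrations (SCNAs) — gains,
losses and loss of heterozygosity (LOH) acquired by the cancer cells.  Two
features of tumor samples complicate the analysis beyond what germline CNV
callers handle: an unknown fraction of admixed normal cells (the admixture
rate $\alpha$) compresses every copy-number signal toward the diploid
baseline, and subclonal heterogeneity means some aberrations are carried by
only a fraction $f$ of the cancer cells.

`scnaclone` takes per-SNP read depths (RD) and lesser-allele frequencies
(LAF, the B-allele frequency mirrored at 0.5) for a tumor–normal pair and
outputs: (1) the sample admixture rate, (2) per-segment somatic allelic
copy numbers, (3) the fraction of tumor cells carrying each subclonal
SCNA, and (4) an event list (gain / loss / LOH / copy-neutral LOH).

## Model and pipeline

### Somatic ratio and copy level

For a genomic segment the *somatic ratio* $r$ is the tumor-to-normal RD
ratio (libraries median-matched first), and the *somatic copy level* is
$s = 2r$.  A clonal segment with integer tumor copy $c$ in a sample with
admixture rate $\alpha$ has expectation

$$ r = \frac{2\alpha + (1-\alpha)\,c}{2}, $$

so $r(2) = 1$ for every $\alpha$: ratio 1 anchors copy 2, which frees the
model from estimating ploidy.  A subclone at copy $c$ in fraction $f$ of
cancer cells (others diploid) has admixture-adjusted ratio
$r_{adj} = (f c + (1-f)\,2)/2$.  This forward model is deliberately
degenerate for multi-copy events — 5 copies in 30%, 4 copies in 45% and
3 copies in 90% of cancer cells all give $r_{adj} = 1.45$ — which is why
subclonality quantification is restricted to one-copy events.

### Stage 1: segmentation of heterozygous-site LAF

The LAF sequence of germline-heterozygous sites is first de-noised by
median-replacement smoothing: a point deviating from its
$\pm$`half_width` neighborhood mean by more than $t$ (default 2) sample
SDs is replaced by the neighborhood median; statistics always use the
original values so the result is order-independent.

Candidate change points are over-detected with circular binary
segmentation (CBS): the maximal two-sample $t$ statistic over circular
arcs, recursively, with permutation p-values at significance 0.01.  Two
implementation points matter:

* **Padding.** Each chromosome's sequence is prolonged with `pad_n = 100`
  pseudo points per end drawn from $N(\bar{x}, s_x)$, a control for
  boundary variance on chromosomes without real change points; change
  points falling in the padding are discarded.  The pseudo-point
  distribution is a documented reconstruction (the natural reading of
  "control for variation"): mean and SD of the observed sequence.
* **Long sequences.** The scan is multiscale — every arc up to 256 points
  is scanned exactly; wider arcs on a coarse grid with local refinement —
  and for segments longer than 1000 points the permutation test is
  replaced by a seeded Monte-Carlo null quantile of the *same* statistic
  on i.i.d. normal data, cached per length bucket.  Observed and null
  statistics use identical scan geometry, so the test stays calibrated;
  the normal stand-in for the permutation null is accurate because the
  statistic is studentized.

CBS deliberately over-detects; a model-selection step then prunes.  Each
candidate $\psi_j$ becomes, after taking cumulative sums of the piecewise
constant model, a hinge regressor $(t-\psi_j)^+$ whose coefficient is the
mean shift.  Candidates enter by forward stepwise selection — each step
adds the candidate whose mean-shift regressor most reduces the model
residual — and the path prefix minimizing a BIC is kept.  (Ordering by
raw correlation with the cumulative-design residual, the literal least-
angle entry order, demonstrably misranks candidates when the detrended
cumulative residual is tent-shaped; residual-reduction ordering selects
the same model family and lets the path prefix reach the best subset.)
Three numerical choices are deliberate:

* the RSS entering the BIC is that of the piecewise-constant fit of the
  LAF itself, not of the cumulative regression — cumulative residuals are
  integrated noise and grossly understate model misfit;
* the default penalty is the inflated change-point form
  $k \log(n)\log(\log n)$ (`bic_variant = "cumseg"`).  The classical
  $k\log n$ penalty measurably overfits here: short (5–10 point) LAF
  excursions caused by depth-dependent mirroring bias pass
  $\mathrm{len}\cdot\Delta^2/\sigma^2 \approx 13 > \log n \approx 9$ and
  survive, splitting genuine events; the inflated penalty (~21 at
  $n = 10^4$) removes them while true events score 50+.

### Stage 2: somatic ratio per segment and refinement

All paired SNPs (heterozygous and homozygous) contribute depth
information.  Depths are modeled as normal approximations to Poisson
counts, $X_i \sim N(R\lambda_i, R\lambda_i)$, $Y_i \sim N(\lambda_i,
\lambda_i)$, and the Geary–Hinkley transform

$$ z_i(r) = \frac{r\,y_i - x_i}{\sqrt{r^2 y_i + x_i}} $$

is approximately standard normal at the true ratio.  The MLE maximizes
$\sum_i \log\phi(z_i(r))$ over $r \in [0.01, 8]$ — a coarse grid (step
0.01) followed by golden-section refinement, which agrees with a dense
0.001 grid to within grid resolution because the objective is smooth and
unimodal.  Per-SNP ratios outside the segment's 5th–95th percentiles are
excluded first (the trim is on the per-SNP ratio; the paper-level
description is ambiguous between ratio and depth).  Geometric-mean and
mean-ratio estimators are provided as cross-checks.

Adjacent segments whose ratios differ by less than $T = 0.05$ are merged
(smallest difference first, deterministic) and the merged ratio
re-estimated from the pooled SNPs, to a fixed point.  Two auxiliary rules
operate here:

* segments with fewer than 5 heterozygous markers are absorbed into the
  ratio-closer neighbor — sub-5-marker aberrations are outside the
  method's stated resolution, and calls that small are dominated by
  mirroring-bias artifacts;
* a short (< 50 het) interior segment whose flanks are merge-compatible
  with *each other* and whose own ratio is within $3T$ of them is an
  over-detection blip inside a single aberration and is folded back in.
  Within-aberration fluctuations from window-level count noise reach
  about $3T$; true small events are protected because their ratio shifts
  are $\geq 4T$ at the admixture rates where they are detectable at all.

### Stage 3: admixture rate by a Bayesian finite mixture

Somatic copy levels of clonal segments cluster at discrete values
$2\alpha + (1-\alpha)c$; subclonal levels sit in between.  The number of
components is chosen by AIC over shared-variance Gaussian mixtures
($K = 3$ minimum: loss, neutral, gain) fitted by multi-start EM to the
*histogram of segment levels* — unweighted, one entry per segment.
Weighting by segment size here lets the neutral mass dominate the
likelihood and collapse distinct aberrant levels.  Centers closer than
0.2 (the 80%-contamination bound) are merged rather than the whole
solution rejected.

Allocation of segments to components is sampled by Markov chain Monte
Carlo (10,000 iterations, 2,000 burn-in): each level is
$N(\mu_k, 0.01)$ given its state — variance 0.01 allows clonal levels to
shift about 0.1 from integer positions — with a conjugate
Dirichlet(1) prior on the mixing weights.  The sweep resamples each
segment's state from its full conditional (acceptance probability 1)
alternating with a Dirichlet draw of the weights; the posterior of a
segment is the fraction of kept iterations in its modal state.  A level
midway between two components (e.g. 1.5 between copies 1 and 2) divides
its iterations and is flagged *candidate subclonal* (posterior < 0.9).

Components are mapped to integer copies on the lattice anchored at
ratio 1 ↔ copy 2.  Candidate $\alpha$ values are generated by
hypothesizing small integer copies for each component; candidates that
would place any center below the double-deletion floor $2\alpha$ are
physically impossible and rejected (this eliminates half-step harmonic
solutions), and the mass-weighted capped lattice misfit selects among the
rest, ties toward less contamination.  Components left far from the
chosen lattice (residual > 0.12) are subclonal-level components; their
segments are excluded from admixture estimation along with low-posterior
segments.  Finally

$$ \hat\alpha = \frac{\sum_j w_j (2-c_j)(s_j-c_j)}{\sum_j w_j (2-c_j)^2}, $$

the closed-form weighted least squares over clonal segments (weights =
SNP counts; copy-2 segments carry no information), clipped to
$[0, 0.8]$.  Estimates at the 0.8 cap are reported without downstream
adjustment — beyond 80% contamination the model is not identifiable.

### Stage 4: subclonality by hypothesis testing

Per segment, normal-sample allelic copies are
$n_B = \mathrm{round}(2R\,\ell_g)$, $n_A = \mathrm{round}(2R(1-\ell_g))$
with $R$ the GC-corrected normal read-count ratio and $\ell_g$ the median
germline LAF.  If the admixture-adjusted ratio exceeds 1 a one-copy gain
is tested (clonal ratio $(n_A+n_B+1)/(n_A+n_B)$), otherwise a one-copy
loss.  Under the null the observed ratio is $N(r_{clonal}, \sigma^2)$;
$\sigma$ is estimated by a seeded nonparametric bootstrap (200 resamples)
of the GH estimator over the segment's SNP pairs, capped at 800 pairs
with $\sqrt{m/n}$ rescaling, and divided by $(1-\alpha)$ because the
adjustment rescales the estimate.  Segments with $p < 0.05$ *and* an
implied fraction strictly inside $(0,1)$ are subclonal with

$$ f = \frac{2r_{adj} - (n_A+n_B)}{(n_{A,t}+n_{B,t}) - (n_A+n_B)}, $$

the changed allele chosen by whether the tumor LAF moved toward 0.5
(gain of lesser / loss of greater allele; ties change the lesser).  The
$f \in (0,1)$ guard matters: without it a clonal double deletion (implied
$f = 2$) would be reported subclonal.  Segments with $|r_{adj}-1| \le
0.05$ are declared copy-neutral and not tested — most false-positive
subclonal calls otherwise arise from copy-neutral segments — except that
a neutral segment whose heterozygous tumor LAF has collapsed below the
midpoint between 0.5 and the admixture floor $\alpha/2$ is labeled
copy-neutral LOH.  Events are labeled LOH when the tumor allelic minimum
is 0 with total $\geq 1$, copy-neutral LOH at total 2.

## The synthetic-data generator

The simulator follows a 7-step protocol: duplicate a template normal
genome; record per-10 kb-window medians and SDs; place SCNA events
(double deletion, LOH, 1- and 2-copy gain; 10 kb up to a whole
chromosome; clonal or subclonal at $f \in \{0.2, 0.4\}$); alter the
window medians inside events by the expected pure-cancer ratio; draw
event-region RD and lesser-allele counts from normal distributions with
those altered medians and the recorded SDs; blend cancer and normal
counts at $\alpha \in \{0.2, 0.4, 0.6\}$; thin binomially to 40× or 20×.
Outside events the pseudo-cancer counts *duplicate* the normal counts —
this matters: the tumor/normal ratio carries no extra noise there, which
is what the protocol specifies and what keeps the background clean.

The template itself is synthetic (the original template genome is
unpublished).  Heterozygous sites are placed by log-normal spacings with
median 453 bp; `sdlog = 1.5` reproduces the reported upper spacing tail
(~15 kb at the 99th percentile) and gives mean spacing ~1.4 kb,
comparable to real het density — a single log-normal cannot match both
reported tail quantiles at once.  Window RD medians/SDs are taken as the
generating values (a real 10 kb window pools ~10⁴ positions, so the
protocol's estimates are essentially exact); lesser-count stats are
estimated from the window's het sites, as stated.  Window-level
multiplicative depth noise has SD 0.1.  Hom sites are interleaved at one
per two het sites.  Because the template is cleaner than real sequencing
data (no mappability artifacts, no GC structure unless requested, exact
window medians), green simulation tests establish correctness of the
machinery — segmentation power, purity recovery, subclonal
quantification — on protocol-faithful data, *not* performance on real
genomes.  Measured recovery rates here tend to sit at or slightly above
the published point estimates for the same reason.

Simulated subclonal events are one-copy types only: the framework can
only characterize one-copy subclonality, and the published recovery
rates presuppose recoverable events.  A known boundary: a solitary
$f = 0.2$ one-copy event at $\alpha = 0.6$ has expected ratio
$1 \pm 0.04$ — inside the merge tolerance $T = 0.05$ — and is therefore
merged into its neutral flanks by the method's own refinement rule; such
events are unrecoverable by design, which is the main cost of the
deliberately conservative merge step at high contamination.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `smoothing$half_width` | 5 points | flank of the outlier-smoothing window |
| `smoothing$t` | 2 | outlier threshold, SD units |
| `segmentation$alpha` | 0.01 | CBS split significance |
| `segmentation$nperm` | 1000 | permutations per split test |
| `segmentation$pad_n` | 100 | pseudo points per chromosome end |
| `segmentation$bic_variant` | "cumseg" | pruning penalty ($k\log n\log\log n$) |
| `ratio$trim` | (5, 95) | per-SNP ratio trim percentiles |
| `ratio$merge_T` | 0.05 | adjacent-segment merge tolerance (ratio units) |
| `admixture$hyper_var` | 0.01 | component variance (levels shift ~0.1) |
| `admixture$min_center_gap` | 0.2 | minimum component separation |
| `admixture$max_alpha` | 0.8 | reporting cap on the admixture rate |
| `admixture$posterior_threshold` | 0.9 | candidate-subclonal cutoff |
| `subclonality$neutral_band` | 0.05 | copy-neutral guard band on $r_{adj}$ |
| `subclonality$p_cutoff` | 0.05 | subclonal classification threshold |

## Known limitations

* Segmentation uses heterozygous-site LAF only; aberrations with few het
  markers (short events, especially double deletions whose mixed LAF
  stays near 0.5) are missed or imprecisely bounded.  Read-depth-window
  local segmentation would complement this and is out of scope.
* Subclonal fractions are only meaningful for one-copy events; multi-copy
  subclones alias onto one-copy solutions (the 1.45 degeneracy above).
* A single clonal cancer population is assumed; multiple coexisting
  clones are not deconvolved.
* Admixture rates above 0.8 are reported but not used for adjustment.
* The Monte-Carlo null for long-sequence CBS assumes exchangeable noise;
  strongly autocorrelated LAF noise (e.g. wave artifacts) would inflate
  detections, which the pruning stage then has to absorb.
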