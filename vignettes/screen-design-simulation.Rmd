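---
title: "Simulating pooled CRISPR screens to guide screen design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pooled CRISPR screens to guide screen design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(screensim)
```

## Why simulate a screen?

Pooled CRISPRi/CRISPRn screens infect a cell population with a lentiviral
sgRNA library, select cells by phenotype — either by FACS-sorting a
fluorescent reporter into "low" and "high" bins, or by letting growth
phenotypes change guide frequencies over several passages — and then
sequence the surviving guide composition. Whether a screen detects its hit
genes depends on design parameters that are expensive to explore
experimentally: the number of cells carried per library element
(*representation*) at infection, selection and sequencing; how extreme the
FACS sort bins are; how many passages a growth screen runs; and the quality
of the sgRNA library itself. `screensim` is a discrete Monte Carlo
simulator of this whole pipeline, built so that these choices can be
compared *in silico* on a known ground truth. Its output is relative — it
ranks designs against each other — not an absolute predictor of any one
screen's performance, because several of its inputs (reporter noise,
library quality) are estimates rather than measured constants.

## The generative model, stage by stage

### Genome

A genome of `n_genes` genes (default 500) assigns each gene a class and a
"true" phenotype $l \in [-1, 1]$: 75% wild type ($l = 0$), 5% negative
controls ($l = 0$, used later as the null set for hit calling and the
noise metric), 10% positive hits with $l$ drawn from a Gaussian
$\mathcal{N}(0.55, 0.2^2)$ clamped to $[0.1, 1.0]$, and 10% negative hits
drawn from the mirrored distribution clamped to $[-1.0, -0.1]$. Clamping
is censoring: out-of-range draws are clipped to the boundary, not redrawn.
Class *counts* are deterministic given `(n_genes, fractions)` — floor of
the product with the remainder distributed in fixed class order — so that
two genomes of equal size are always comparable.

Each gene also receives a knockdown–phenotype response $f(x)$ mapping
knockdown fraction $x$ to the fraction of $l$ realised. 75% of genes are
*linear* ($f(x) = x$); 25% are *sigmoidal* (switch-like), with

$$
f(x) =
\begin{cases}
0, & x \le p - k\\
1, & x \ge p + k\\
\frac{1}{2}\!\left(\frac{\operatorname{sign}(\delta)\,1.05\,|\delta|}{|\delta| + 1} + 1\right), & p - k < x < p + k
\end{cases}
\qquad
\delta = \frac{x - p}{\min(p,\ \min(1 - p,\ k))}
$$

where the inflection point $p \sim \mathcal{N}(0.8, 0.2^2)$ and half-width
$k \sim \mathcal{N}(0.1, 0.05^2)$. Numerical choices here:

* **Parameter sanitisation.** The raw Gaussians can produce $k \le 0$ or
  $p \notin (0,1)$, which make $\delta$ ill-defined. Draws are rejected
  until $k \ge 0.01$ and $0.05 \le p \le 0.99$; rejection barely distorts
  the bulk of either distribution.
* **`sign(0) = 0`**, so $f(p) = \tfrac12$ exactly.
* **Edge discontinuities are kept.** $f$ jumps from 0.2375/0.7625 to 0/1
  at $x = p \mp k$ when $k \le \min(p, 1-p)$; we do not smooth them.
* **Range clipping.** When $k > \min(p, 1 - p)$, $|\delta|$ can exceed 20
  near a window edge and the middle branch then leaves $[0, 1]$ slightly
  (e.g. $f = -0.013$). Since $f$ is by construction the *fraction* of the
  full phenotype realised, the middle branch is clipped to $[0, 1]$; this
  only triggers for extreme tail draws of $(p, k)$.

A cell's (noise-free) phenotype is $\varphi = l \cdot f(x)$ at its
realised knockdown $x$.

### sgRNA library

Each gene is targeted by $m$ guides (default 5). Guide activity is
bimodal: 90% of guides are highly active, 10% have low activity
($\mathcal{N}(0.05, 0.07^2)$, clipped to $[0,1]$ — essentially
indistinguishable from controls). In CRISPRi mode, high-activity guides
draw their knockdown efficiency from $\mathcal{N}(0.90, 0.1^2)$; in
CRISPRn mode they cut with efficiency exactly 1.0 and the phenotypic
consequence is decided per cell at infection (below). Plasmid frequencies
are log-normal with the log-scale $\sigma$ solved from the requirement
that the 95th-percentile guide is 10 times as frequent as the
5th-percentile guide ($\sigma = \ln 10 / (z_{0.95} - z_{0.05}) \approx
0.70$); the log-scale mean is irrelevant because frequencies are
normalised to sum to one.

### Infection

`representation × n_guides` cells are exposed to virus; each receives
$\mathrm{Poisson}(\lambda)$ integrations ($\lambda = 0.25$ by default) and
only single-integrant cells are kept — a fraction $\lambda e^{-\lambda}
\approx 19.5\%$. Retained cells draw their guide from the plasmid
frequencies. CRISPRi cells realise the guide's knockdown efficiency
directly. CRISPRn cells with an active guide realise a *heritable*
knockout outcome: assuming 2/3 of repair events at a cut locus cause a
frameshift in a diploid cell, a cell gets no knockout, a monoallelic
knockout (knockdown 0.5) or a biallelic knockout (knockdown 1.0) with
probabilities 1/9, 4/9 and 4/9. The realised knockdown is mapped through
$f$ like any CRISPRi knockdown.

Cells are tracked as counts per (guide, realised knockdown) bucket.
Because every cell in a bucket is statistically identical, this is exactly
equivalent to per-cell tracking and orders of magnitude faster.

### FACS selection

The pool is bottlenecked to `representation × n_guides` cells (multinomial
resampling with replacement — the standard approximation when the source
pool is large), each cell's *observed* phenotype is drawn as
$\varphi + \mathcal{N}(0, \sigma^2)$, and the bottom and top
`bin_fraction` of cells by observed phenotype become the two comparison
bins, each of exactly `round(bin_fraction × bottleneck)` cells. The noise
is realised literally per cell — one Gaussian draw per cell, a global
ranking, and order-statistic tails — which is the reference behaviour any
faster approximation would have to match, and is itself fast enough in
vectorised R (about 0.3 s for a default 250,000-cell screen). Ties in
observed phenotype occur only at $\sigma = 0$ and are broken in random
order.

$\sigma$ defaults to 1.0 phenotype units: reporter noise in which even the
strongest phenotype ($|l| = 1$) is only one noise SD from wild type. This
is a deliberately pessimistic-but-realistic regime for single-cell
fluorescence; it is the one tunable whose value most affects absolute
metric values, which is why comparisons across designs, not absolute
numbers, are the supported use.

### Growth selection

The t0 comparison population is the post-infection pool subsampled to the
bottleneck size, so both endpoints carry comparable sampling noise, as
they do in a real screen where both time points are sequenced. Then, for
each of $n$ passages: in the time wild-type cells divide once, a cell with
phenotype $\varphi > 0$ divides twice (4 cells) with probability $\varphi$
and once otherwise, while a cell with $\varphi < 0$ fails to divide (1
cell) with probability $|\varphi|$; the pool is then bottlenecked back
down. Per bucket this is a single binomial draw of extreme-behaviour
cells, distributionally identical to the per-cell rule; the expected
per-passage growth factor is $2 + 2\varphi$ for $\varphi \ge 0$ and $2 -
|\varphi|$ for $\varphi < 0$. The bottleneck is applied after every
passage including the last, so tn is the pool after the $n$-th subsample.

### Sequencing

Each bin is sequenced to `representation × n_guides` reads by multinomial
sampling with the bin's guide frequencies as weights — knockdown buckets
of one guide are merged first, since sequencing sees guides, not repair
outcomes. Multinomial (with replacement) sampling reflects that PCR
amplification makes reads exchangeable draws from the library composition.
Both bins get the same depth.

## Hit calling and evaluation

Guide phenotypes are $\log_2$ ratios of pseudocounted bin frequencies,
bin 2 (high / tn) over bin 1 (low / t0). The default pseudocount of 0.5 is
added to every guide in both bins, keeping fully depleted guides
informative; guides with zero reads in *both* bins carry no information
and are dropped. Gene phenotypes average the member guides' $\log_2$ fold
changes; a two-sided Mann–Whitney rank-sum test against all non-dropped
negative-control guides gives the p-value (exact for small tie-free
samples, normal approximation with tie and continuity corrections
otherwise — the latter is what a 5-vs-125 comparison uses); genes are
ranked by $|\text{phenotype}| \times -\log_{10} p$, with $-\log_{10} p$
capped at 300 and score ties broken by gene id. Genes whose guides all
dropped score 0.

Screen performance against the known truth is quantified as:

* **Top-`n` overlap** (default 50): fraction of the called top-`n` genes
  that are among the actual top-`n` by $|l|$.
* **AUPRC** with both hit classes as positives and wild-type plus
  negative-control genes as negatives, using a lower trapezoidal
  estimator: a precision–recall point per achievable threshold (tied
  scores collapse), anchored at recall 0 with the first point's precision,
  linearly interpolated — chosen over AUROC because hits are under 20% of
  genes.
* **Signal / noise / SNR.** A hit gene's signal is the mean over its
  non-dropped guides of $\log_2\text{FC} / \text{theoretical phenotype}$,
  where the theoretical phenotype maps the guide's *expected* knockdown
  through $l \cdot f(\cdot)$ — for active CRISPRn guides the expectation
  over the 1/9–4/9–4/9 outcome mix, so the per-guide reference is
  deterministic even though outcomes are per cell. Screen signal is the
  median over hit genes; noise is the SD of negative-control guide
  phenotypes; SNR is their ratio (undefined, and reported missing, at zero
  noise). Guides with theoretical phenotype 0 are excluded from the
  signal ratio.

## Sweeps and reproducibility

`run_screen(config, seed)` is bit-reproducible. `run_sweep()` expands a
named list of parameter grids (dotted paths such as
`facs.bin_fraction`; `representation` addresses all three stage
representations jointly; `selection.<param>` addresses whichever selection
stage is active), derives every replicate's seed as a pure Lehmer-hash
function of (base seed, cell index, replicate index), and reports per-cell
means with normal-approximation confidence intervals. Failed runs are
recorded and skipped, not fatal.

```{r snr-curve, eval = FALSE}
curve <- snr_curve(screen_config(), replicates = 25, base_seed = 1)
curve[, c("bin_fraction", "snr_mean")]
```

With the default conditions (500 genes, 5 guides/gene, 100×
representation at every stage, $\sigma = 1$) the mean SNR over bin
fractions 5–45% peaks at a bin fraction of about 25%, with signal and
noise each decreasing monotonically in bin size — small bins hold the most
extreme cells (strong signal) but few of them (heavy sampling noise).
Because the 25–40% stretch of the curve is nearly flat, resolving the
argmax reliably needs replication: we use 10 replicates per grid point for
quick qualitative checks and 80 in `scripts/acceptance.R`, where the
argmax itself is the reported quantity.

## What the generator does and does not emulate

The synthetic screens reproduce the mechanisms that dominate real screen
performance: Poisson infection statistics, representation bottlenecks at
every stage ("jackpot" sampling noise), bimodal guide activity, log-normal
library skew, heritable CRISPRn genotypes versus graded CRISPRi
knockdown, and reporter noise in FACS. They deliberately omit: off-target
activity (negligible for CRISPR relative to RNAi), sequence-dependent
guide behaviour, gene–gene interactions, positional effects, sequencing
error and PCR jackpotting beyond multinomial noise, cell death as distinct
from non-division, and any absolute calibration of reporter noise.
Passing tests therefore demonstrate correct implementation of this model
and correct relative parameter rankings under it — not absolute
performance guarantees for any particular experimental system.

## Problem sizes used in the checks

The test suite runs analytic-oracle checks at $10^5$–$10^6$ cells or
draws (retention fraction, knockout outcome frequencies, growth factors,
library spread), estimator-vs-oracle checks by exhaustive enumeration
(Mann–Whitney for all group sizes with $n_1 + n_2 \le 10$; AUPRC on 100
random ≤20-gene instances), and end-to-end screens at 500 genes with 10
replicates per swept grid point (25–80 replicates where an argmax is the
quantity of interest). These sizes were chosen so that Monte Carlo error
is small relative to the tolerances being asserted.

## Known limitations

* Absolute signal and noise values depend on the chosen $\sigma$ and
  sequencing depth; only relative comparisons across designs are
  meaningful.
* The multinomial bottleneck (sampling with replacement) slightly
  understates variance relative to without-replacement subsampling when
  the bottleneck is a large fraction of the pool; at the default 5× gap
  between pool and bottleneck the difference is negligible.
* CRISPRa screens can be emulated only by reinterpreting the knockdown
  axis as overexpression; there is no separate mechanism for activation.
* Negative-control genes' own p-values are computed against a null set
  that includes their own guides; with 25 control genes × 5 guides the
  self-contribution is 4%, immaterial for ranking.
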