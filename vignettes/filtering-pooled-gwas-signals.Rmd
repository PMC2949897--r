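---
title: "Filtering and visualising pooling-based GWAS signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering and visualising pooling-based GWAS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptracks)
```

## The measurement model

In a DNA-pooling association design, pooled case DNA and pooled control DNA
are hybridised on separate arrays. At each SNP an array reports two channel
intensities, one per allele. The working assumption — standard for pooled
allelotyping — is that the channel intensities are proportional to the
allele content of the pool, so the relative allele signal

$$\mathrm{RAS} = \frac{A}{A+B} \in [0,1]$$

estimates the pool's A-allele frequency. Each array contributes one RAS
observation per SNP; we do not model probe-level replicates (arrays are the
replication unit). Association evidence at a SNP combines:

* the **signed mean-RAS difference**
  $d = \overline{\mathrm{RAS}}_{\text{case}} -
  \overline{\mathrm{RAS}}_{\text{control}}$, whose sign identifies the
  allele predominant in cases;
* a **Welch two-sample t statistic** on per-array RAS values with
  Welch–Satterthwaite degrees of freedom (chosen over the pooled-variance t
  because case and control pools have no reason to share an error
  variance; it is the conservative default when the upstream analysis
  software's internal test is unspecified);
* the genome-wide **rank**. `pool_analyze()` ranks by ascending p-value
  (equivalently descending |t|), breaking ties by map order so results are
  deterministic.

Degenerate inputs are handled explicitly: a zero total intensity $A+B=0$ is
an error naming the SNP and array; zero variance in both groups gives
$t=0,\ p=1$ at equal means, and at unequal means an infinite statistic
whose p-value is floored at the smallest positive double so it stays inside
the contracted $(0,1]$ range.

## Height tracks and the three filters

Display values live on a 0–100 scale where 100 is a fully saturated
signal. `scale_to_height()` maps scores linearly against a user-stated
maximum expected value, p-values through $-\log_{10}p$ against a maximum
expected $-\log_{10}p$ (default 8, i.e. $p=10^{-8}$ saturates), and ranks
through $100\,(N-\text{rank}+1)/N$ so rank 1 saturates. We filter scaled
heights, not raw values: the filters are display-space operations and this
keeps one parameterisation across score, rank and p-value inputs.

**Logarithmic filter.** $r_\mathrm{new} = s\,2^{f\,(r/s-1)}$ with
$s = 100$. The map is strictly increasing, fixes $r=s$, and sends $r=0$ to
$s\,2^{-f} > 0$: background is compressed hard but never eliminated, so no
SNP silently disappears. $f$ (dimensionless, default 50) sets the
stringency; at $f=50$, a height of 70 becomes $100\cdot2^{-15}\approx
0.003$ while 95 becomes $100\cdot2^{-2.5}\approx 18$ — five orders of
magnitude of separation from 25 points of input difference.

**Best-of-window sliding mean.** Each SNP receives the mean of the best
$m-d$ of the window made of itself and the following $m-1$ SNPs. Windows
are forward-looking, never cross chromosome boundaries, and at a chromosome
end they shrink (and the best-count shrinks with them) rather than wrap or
pad — shrinking avoids inventing data. With $m=1$ the filter is the
identity; with $d=0$ it is a plain forward moving average. It rewards runs
of consecutive high SNPs — the signature of a genuine locus in dense data —
over isolated spikes.

**Cutoff and stretch.** With $M$ the track maximum and
$t = (p_{\mathrm{cut}}/100)\,M$: heights $\le t$ become 0, the rest are
stretched by $100\,(r-t)/(M-t)$ so the maximum is 100 again. The threshold
is relative to the *whole-track* maximum by default; a `per_chromosome`
flag computes it per chromosome instead (per-chromosome normalisation can
promote noise on chromosomes with no real signal, hence the whole-track
default). An all-zero track passes through unchanged.

A chain such as `list(step_log(50), step_window(5, 0), step_cutoff(20))`
applies strictly left to right; all filters preserve track length and
(chrom, pos, id) identity and keep outputs in $[0,100]$.

## Q-Q tables and genomic control

The Q-Q module sorts p-values ascending and attaches expected uniform
quantiles. We use the midpoint convention $(i-0.5)/n$ by default (it is
symmetric and keeps both endpoints off 0 and 1); $i/(n+1)$ is available as
an option. For p-values from a 2-df chi-square test the conversions have
closed forms — $\chi^2 = -2\ln p$ and survival $e^{-x/2}$ — so the
genomic-control correction needs no special functions: the inflation
factor is $\lambda = \mathrm{median}(\chi^2)/(2\ln 2)$, statistics are
divided by $\lambda$, and corrected p-values recomputed. $\lambda$ is
clamped below at 1 by the usual genomic-control convention (deflation is
not "corrected" into inflation); the clamp is toggleable. Corrections for
other degrees of freedom, and for score data, are out of scope. $p=0$
inputs are rejected rather than floored: a zero p-value signals an
upstream problem that flooring would hide.

## Rendering

The tool-facing renderers rasterise directly into pixel arrays written
with `png::writePNG`: every SNP is a vertical line whose pixel height is
proportional to its track height (100 spans the full drawable height), the
Manhattan view concatenates chromosomes in map order with alternating
colours, and the Q-Q view plots $-\log_{10}$ expected vs observed with the
identity diagonal. Direct rasterisation was chosen deliberately: the
files contain no timestamps or device-dependent metadata, so identical
inputs give byte-identical PNGs — a testable contract — and pixel-level
assertions (saturation, monotonicity of line heights) are exact. The
default x-mapping spaces SNPs equally by index, matching the dense
per-SNP-line display; base-pair spacing is an option. For interactive
work, `autoplot()` methods and `plot_manhattan()` produce conventional
ggplot2 figures. Image dimensions default to height 200 px with
one pixel column per SNP (minimum width 64); they are configuration, not a
contract.

## Input dialects

Association tables are read from arbitrary tab- or whitespace-delimited
text via column presets (INI sections naming the four column indices, the
delimiter policy, the header mode, the value kind and the maximum expected
value). Header auto-detection treats the first line as a header iff its
value field does not parse as a number — robust for both headered
(PLINK-style) and headerless (GenePool-style) files and exercised both
ways in the tests. Chromosomes are ordered 1–22, X, Y, MT with "chr"
prefixes stripped; positions are 1-based; duplicate (chrom, pos, id) rows
are rejected as malformed rather than merged. The shipped `plink_assoc`
preset mirrors real PLINK `--assoc` columns; the `eigenstrat` preset is an
approximation that carries map coordinates (real EIGENSTRAT per-SNP output
does not), and both are exact for files the package itself writes.

## The synthetic-data generator

`simulate_pooled_intensities()` draws a true A-allele frequency
$q \sim U(0.05, 0.95)$ per SNP; spiked SNPs shift the case pool by
$\delta$ (clamped into $(0.01, 0.99)$). Channel means are
$I\,q$ and $I\,(1-q)$ with total intensity $I = 2000$ (arbitrary units —
RAS is scale-free), each multiplied by lognormal noise
$e^{N(0,\sigma)}$ with $\sigma = 0.02$ by default. Multiplicative noise
was chosen over additive Gaussian because intensities are non-negative and
array noise scales with signal; 2% channel noise and 4 arrays per group
reflect a small pooling study. In the noiseless limit RAS recovers $q$
exactly, which the tests use as an identity oracle.

`simulate_score_table()` emulates the background-plus-peak structure of a
noisy genome-wide score plot: background scores $U(0, 70)$, spiked-window
scores $U(90, 100)$, on a 5,000-SNP chromosome with a 10-SNP spike in the
standard scenario. These bands give a clean separation for the default
filter chain and parameterise the tests, not the tool.

What the generator does **not** emulate: linkage disequilibrium (adjacent
background SNPs are independent, whereas real loci produce correlated
runs — real peaks are easier for the window filter than simulated ones),
batch and plate effects, probe-level variation, allele-specific
hybridisation bias, and differential noise between pools. Passing tests
therefore demonstrate the algorithmic contracts and calibration under a
clean noise model, not performance on any particular array platform.

## Problem sizes and determinism

All simulations are deterministic given a seed. The test suite runs the
filter oracle on 500 random tracks of length up to 200, the chain
separation on a 5,000-SNP chromosome, genomic-control calibration on
10,000 null p-values, and sign recovery over 100 replicate pooling
simulations — sizes chosen to exercise every code path at desk scale while
keeping the whole suite fast enough to run on every change. The
`scripts/acceptance.R` report recomputes the same quantities from scratch
at the same sizes.

## Known limitations

* Raw array files (CEL/Illumina exports) are not parsed; the package
  starts from intensity tables or association result text files.
* The Welch t on a handful of arrays has low power; the package reports
  it faithfully but small pooling studies should treat per-SNP p-values
  as screening hints, which is why ranks and signed RAS differences are
  first-class outputs.
* Genomic control is implemented only for 2-df chi-square p-values.
* Track bitmaps use one colour per image and no axes; they are screening
  visuals, not publication figures — use the ggplot2 layer for those.
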