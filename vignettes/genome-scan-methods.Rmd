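---
title: "Methods: genotype likelihoods, kernel-smoothed scans, and bootstrap significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype likelihoods, kernel-smoothed scans, and bootstrap significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

radscan implements a population-genomic scan for reduced-representation
(RAD-seq) data: maximum-likelihood diploid genotype calling from per-site
nucleotide read counts, per-site diversity and differentiation statistics,
Gaussian kernel smoothing along the genome, bootstrap significance for
smoothed windows, and delineation of candidate regions of selection. A
built-in simulator generates read-count datasets with known truth that
emulate a replicate oceanic/freshwater study design — two nearly panmictic
"ancestral" populations and three independently founded derived
populations — so the whole pipeline can be exercised and validated without
any external data.

## The genotype-calling model

At one genomic site in one individual, let $n = n_1 + n_2 + n_3 + n_4$ be
the reads showing each nucleotide (ambiguous reads are excluded upstream).
A diploid genotype is one of ten hypotheses: four homozygotes and six
heterozygotes. Under a multinomial read model with sequencing error rate
$\varepsilon$, a homozygote $i/i$ emits nucleotide $i$ with probability
$1 - \tfrac{3}{4}\varepsilon$ and each other nucleotide with probability
$\varepsilon/4$; a heterozygote $i/j$ emits each allele with probability
$\tfrac{1}{2} - \tfrac{\varepsilon}{4}$ and each other nucleotide with
$\varepsilon/4$. The log-likelihood of a hypothesis is the multinomial
log-probability of the observed counts. The multinomial coefficient is
included so likelihoods are genuine probabilities; it cancels in every
likelihood ratio.

$\varepsilon$ is not assumed constant across the genome: it is profiled by
maximum likelihood *per site and per hypothesis*. The profile has closed
forms — $\hat\varepsilon = 4(n - n_i)/(3n)$ for homozygote $i/i$ and
$\hat\varepsilon = 2(n - n_i - n_j)/n$ for heterozygote $i/j$ — which the
test suite checks against a dense grid search at $10^{-4}$ resolution. The
admissible range is capped at `eps_max = 1` by default: the homozygote
category probabilities would stay valid up to $4/3$ and the heterozygote's
up to $2$, but error rates above 1 have no physical meaning. Each top
hypothesis carries its own $\hat\varepsilon$; the likelihood-ratio test
between the two best hypotheses is still treated as having one degree of
freedom.

A genotype is assigned only when that test is significant at level
$\alpha$ (default 0.05, critical value $\chi^2_1(0.95) = 3.841459$).
Low-coverage sites therefore drop out by failing the test rather than by a
fixed depth cutoff: a single read can never be assigned
($\mathrm{LRT} = 2\ln 2 \approx 1.386$), while twelve concordant reads can
($\approx 16.64$). Exact ties between the two best hypotheses give
$\mathrm{LRT} = 0$ and an unassigned call; ties elsewhere in the ranking
are broken by the fixed nucleotide order A < C < G < T so results are
deterministic. Sites with no reads are flagged `no_data`. Hard calls only:
carrying per-genotype uncertainty into the downstream statistics is out of
scope here.

## Per-site statistics

A site is a *SNP* within a comparison when at least two alleles segregate
among assigned genotypes of the pooled sample.

**Nucleotide diversity.** $\pi = 1 - \sum_i n_i(n_i-1)/\big(n(n-1)\big)$,
the unbiased probability that two allele copies drawn without replacement
differ (equivalent to expected heterozygosity). The plug-in form
$1 - \sum_i \hat p_i^2$ is available by option.

**Observed heterozygosity.** $H$ = heterozygous fraction of assigned
diploid genotypes.

**Differentiation.** $F_{ST} = 1 - \sum_j w_j \pi_j / \pi_T$, where
$\pi_j$ is the diversity within population $j$, $\pi_T$ the diversity of
the pooled sample, and $w_j \propto n_j(n_j - 1)$ weights populations by
their number of within-population allele pairs, accommodating the unequal
per-site sample sizes that arise when genotypes fail assignment
($w_j \propto n_j$ is selectable). Two design choices deserve emphasis:

* Inside the $F_{ST}$ ratio the diversities use the plug-in form by
  default. With a common denominator within and across populations,
  identical populations give exactly 0 and fixed differences exactly 1 —
  the identities a differentiation measure should satisfy and that the
  test suite asserts. Substituting the unbiased estimator
  (`pi_form = "unbiased"`) makes $F_{ST}$ slightly negative for identical
  finite samples, because the without-replacement correction is applied to
  different sample sizes within versus across. The reported per-site `pi`
  column always uses the unbiased form.
* Negative values (within-diversity exceeding pooled diversity) are
  reported as-is, never clamped.

The estimator is rank-concordant (Spearman > 0.95 in the test suite) with
a Weir–Cockerham-style variance-partitioning estimator on simulated SNPs,
but the two are not numerically identical; in particular, for two
populations with the same drift parameter $F$ this ratio estimator has
large-sample expectation $(F/2)/(1 - F/2)$ rather than $F$, since pooling
a pair of populations dilutes between-population pairs. The simulator
tests encode that closed form.

**Private alleles.** $\rho_j = 1$ when some allele occurs in population
$j$ and in no other population of the comparison *and* every population
has at least one assigned genotype at the site — otherwise absence of
evidence would masquerade as exclusivity.

**Per-SNP significance.** A goodness-of-fit $G$ test on the
allele-by-population table, $G = 2\sum O \ln(O/E)$ with
$(a-1)(r-1)$ degrees of freedom, no Williams or continuity correction;
p-values are corrected across SNPs with the Benjamini–Hochberg step-up
procedure, which remains valid under the positive dependence expected
among linked SNPs.

Monomorphic sites keep $\pi = 0$ and $H = 0$ and contribute to the
diversity tracks; $F_{ST}$, $\rho$ and $G$ are undefined there and those
tracks average over SNPs only.

## Kernel smoothing

Per-site statistics are noisy; regional signal is extracted with a
truncated-Gaussian moving average. The window value at centre $c$ is

$$\bar x_c = \frac{\sum_k x_k \, e^{-(p_k-c)^2/2\sigma^2}\, w(n_k)}
                  {\sum_k e^{-(p_k-c)^2/2\sigma^2}\, w(n_k)},$$

with bandwidth $\sigma = 150$ kb by default, truncation at $3\sigma$
(beyond which the relative weight is below ~0.011), and centres every
100 kb starting at step/2 — a fixed grid origin so outputs are bit-for-bit
reproducible. Because assignment failures make the allele sample size
$n_k$ vary across sites, each site is additionally weighted by
$w(n_k) = n_k(n_k-1)$, an inverse-variance-style weight for
pairwise-comparison estimators ($n_k$ and $n_k - 1$ are selectable; every
smoothing invariant holds for any positive weight). Only sequenced sites
can contribute — never-sequenced positions are simply absent — and windows
with no contributing site are reported as missing, not zero. Smoothing is
linear and every window value is a convex combination of its contributing
sites; the test suite checks both properties plus exact agreement with a
brute-force double-loop implementation.

**Windowed Tajima's D.** For near-equilibrium pools (in the emulated
design, the combined oceanic pair), each window collects the sites within
$\sigma$ of its centre (a $2\sigma = 300$ kb window), counts SNPs $S$,
sums per-site $\pi$, and evaluates the standard 1989 statistic at
$n = \mathrm{round}(\bar n_k)$. $D$ is undefined for $S < 2$ or $n < 3$.
The window half-width is configurable; note that a literal reading of
"300 bp" for a $2\sigma$ window would contradict $\sigma = 150$ kb by
three orders of magnitude, so the kb scale is used.

## Bootstrap significance and regions

Significance of a smoothed window is assessed by genome-wide resampling:
each replicate reassigns every contributing site a (value, $n_k$) pair
drawn with replacement from the genome-wide pool of per-site values of the
same statistic and recomputes the weighted average with the original
kernel weights. This null preserves the window geometry, the genome-wide
distribution of the statistic, and its sample-size structure, while
destroying spatial autocorrelation — so small p-values flag regions whose
coherent elevation or reduction cannot be produced by independently
shuffled sites. `p_elevated` and `p_reduced` are the fractions of
replicates at or beyond the observed value; replicates exactly equal to it
count toward both tails (conservative).

Replicates escalate in stages: starting from a statistic-specific initial
count (100 for $\pi$/$H$, 1,000 for $D$, 10,000 for $F_{ST}$/$\rho$), the
count is multiplied by 10 whenever the minority tail holds fewer than 10
exceedances, up to a cap ($10^6$ for $\pi$/$H$/$D$, $10^7$ for
$F_{ST}$/$\rho$). A window with a zero tail at the cap is reported as 0
with the flag `"<1/R"`; a $(k+1)/(R+1)$-style estimate was considered and
rejected as the default to keep the flagged-zero semantics explicit. A
window whose observed value exceeds every pool value is assigned its zero
tail without sampling — no convex combination of pool values can cross it.
Each window and escalation round draws from its own substream seeded
deterministically from one master seed (a splitmix64 counter stream), so
results are independent of processing order and bit-reproducible.

Candidate regions are runs of consecutive grid windows significant at
$p < 10^{-5}$ in **all** required tracks — for the parallel-selection
question, the overall oceanic–freshwater comparison *and* all six pairwise
freshwater–oceanic comparisons — extended by $2\sigma$ (300 kb) beyond the
outermost significant centres, clipped to the chromosome, with overlapping
extensions merged. Gap tolerance inside a run is 0 windows by default
(configurable). The margins deliberately cast a wide net: a gene under a
peak's shoulder may drive the averaged signal without sitting on the most
significant window.

## The simulator

`sim_config()` describes the emulated study; its defaults are the study
conditions the test suite runs under.

| parameter | default | meaning |
|---|---|---|
| genome | 3 × 5 Mb | chromosome layout |
| `rad_spacing` | 20 kb | mean distance between RAD tag starts (a density echoing ~22,830 restriction sites over a ~460 Mb genome) |
| `sites_per_tag` | 30 | sequenced nucleotide sites per tag |
| populations | 2 oceanic + 3 freshwater, 20 diploids each | the replicate design |
| `f` | 0.005 oceanic; 0.15/0.10/0.12 freshwater | Balding–Nichols drift per population |
| `poly_rate` | 0.05 | probability a site is ancestrally polymorphic |
| `freq_grid` | 0.025…0.975 | ancestral frequency grid, sampled ∝ 1/p |
| `coverage` | 7 | mean read depth per individual (Poisson) |
| `error` | 0.01 | true sequencing error rate |
| `dropout_freq` | 0.02 | restriction-site (null-allele) frequency per tag |

Population frequencies follow the Balding–Nichols model:
$p_j \sim \mathrm{Beta}\big(p_0(1-F)/F,\ (1-p_0)(1-F)/F\big)$, so
$E[p_j] = p_0$ and $\mathrm{Var}[p_j] = F p_0(1-p_0)$. This is the minimal
stand-in for independent founding events from a common ancestral pool: it
reproduces the magnitude structure of the design (ancestral populations
nearly identical, derived populations drifted an order of magnitude more)
without modelling demography explicitly. The drift defaults were chosen
once for that qualitative structure; the resulting per-SNP mean $F_{ST}$
values at $n = 40$ alleles per pool are whatever the estimator produces
and are reported, not tuned. The ancestral polymorphism rate (0.05 with a
1/p spectrum) was likewise chosen once so that a $6\sigma$ window holds a
few dozen sample-detectable SNPs — enough for stable smoothed tracks at
this genome scale.

Three selection scenarios shape local frequencies:

* **parallel sweep** — the *same* ancestrally rare allele driven to
  frequency 0.95 in all three derived populations (default: chrI,
  600 kb): elevated overall and pairwise freshwater–oceanic $F_{ST}$,
  little among-freshwater differentiation;
* **non-parallel sweep** — an independently chosen allele per derived
  population (chrII): elevated among-freshwater $F_{ST}$;
* **balancing selection** — all populations pulled to frequency 0.5
  (chrIII): elevated diversity, reduced differentiation.

Hitchhiking decay is modelled as a linear frequency taper (150 kb) at the
interval edges, not a coalescent sweep — sufficient to create the
peak-and-margin geometry the scan must detect, which is what the tests
exercise. Overlapping scenario footprints are rejected.

Reads are emitted generatively with the same multinomial error model the
caller inverts: HWE genotypes from the population frequency, Poisson depth,
and per-tag dropout alleles. An individual homozygous for dropout yields no
reads across the tag; a heterozygous-dropout individual retains one random
haplotype at half the expected depth, so true heterozygotes read as
homozygotes. This reproduces the known downward bias of restriction-site
polymorphism on diversity: averaging over the two retention outcomes
always lowers the expected $\pi$ (the duplicated pair of copies is
forcibly identical), a mechanism the tests verify exactly and in
aggregate. All randomness flows from one master seed through fixed,
named substreams.

**What the simulator does not emulate**: linkage disequilibrium and
haplotype structure within or between tags (sites are conditionally
independent given the population frequency), post-founding gene flow from
derived populations back to the ancestral pool, allele-specific read bias,
base-quality variation, indels, and paralogous alignment artifacts.
Passing tests therefore demonstrate that the estimators and the scan
machinery behave correctly under the stated generative model — not that
the pipeline is robust to every artifact of real libraries.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-depth sites are `no_data`;
$\pi$ needs $n \ge 2$; $F_{ST}$ needs two populations with $n_j \ge 2$ and
a polymorphic pool; degenerate $G$ tables return `NA`; empty windows are
missing, not zero. Comparisons with equal likelihoods or values resolve by
fixed order, never by RNG.

The validation suite runs the full pipeline on the default 3 × 5 Mb,
100-individual design — about 23,000 sites and 2.3 million genotype calls
per replicate — across 20 master seeds for sweep recovery, with the
bootstrap plan scaled to 1,000 initial replicates and a cap of $10^5$
(sufficient to resolve the $10^{-5}$ window threshold; the
full-scale defaults above remain the package defaults). The per-window
bootstrap and the ten-hypothesis likelihood profile are implemented in
C++ (see `src/kernels.cpp`); everything else is vectorised R.

## Limitations

Hard genotype calls discard uncertainty; downstream statistics inherit the
resulting small biases (unassigned heterozygotes, dropout substitution),
which are documented and directional rather than corrected. The bootstrap
null treats sites as exchangeable genome-wide, so it calibrates
"different from the genome average" rather than any explicit
population-genetic null model. No haplotype-based statistics (LD, EHH) are
computed: short reads anchored at restriction sites do not phase across
tags.
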