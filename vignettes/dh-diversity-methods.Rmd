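---
title: "Methods: diversity loss and selection during doubled-haploid production"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity loss and selection during doubled-haploid production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhdrift)
```

## The problem

A doubled-haploid (DH) library and a genotyped landrace (LR) sample are
two *independent* draws from the same ancestral accession: the genotyped
LR individuals are not the parents of the DH lines. A naive binomial
comparison of LR and DH allele frequencies therefore understates the
sampling variance and over-calls outliers. `dhdrift` instead models three
chained binomial sampling events per site:

1. **LR genotyping** — `n_L` chromosomes drawn at the ancestral frequency;
2. **DH pool survival** — `n_H` lines survive haploid induction, each
   line's single (homozygous) allele drawn at the ancestral frequency;
3. **DH genotyping** — `n_D` chromosomes (i.e. `n_D / 2` lines) drawn
   from the surviving pool.

Both outlier statistics are built on this scheme, so "outlier" always
means *more frequency change than three-stage neutral sampling explains*.

## The two outlier tests

**aSFS test.** For candidate ancestral frequency $j$ on a grid and pool
count $i \in \{0, \dots, n_H\}$ the likelihood surface is
$$I_{ji} = P(d \mid n_D, i/n_H)\, P(i \mid n_H, j)\, P(l \mid n_L, j),$$
with $P(k, n, p)$ the binomial mass. The surface is maximized over
$(j, i)$ jointly (the default; `ml_mode = "marginal"` instead sums over
$i$ first — both are exposed because the choice between profiling and
marginalizing the pool count is genuinely open, and on the default grid
they rarely disagree by more than one grid step). At the estimate
$\hat p$, the neutral DH-count distribution
$$P(s) = \sum_{i=0}^{n_H} P(s \mid n_D, i/n_H)\, P(i \mid n_H, \hat p)$$
gives a central 95% interval; a site is an outlier (class `below` or
`above`) when the observed $d$ falls outside.

**Joint-probability test.** The probability of the pair $(l, d)$ under
neutrality, with the unknown ancestral frequency integrated over a
conjugate Beta($\alpha$, $\beta$) prior:
$$P = \binom{n_L}{l}\binom{n_D}{d} \sum_{i=0}^{n_H} \binom{n_H}{i}
\frac{B(k+\alpha,\, n-k+\beta)}{B(\alpha, \beta)}
\left(\tfrac{i}{n_H}\right)^{d}\left(1-\tfrac{i}{n_H}\right)^{n_D-d},
\qquad k = i + l,\; n = n_L + n_H.$$
The default $\alpha = \beta = 1/2$ is the Jeffreys prior. Within an
accession the top 5% of $-\log_{10}(P)$ are flagged. The tests are
complementary: the aSFS test conditions on a point estimate of the
ancestral frequency and asks whether $d$ is surprising; the joint test
scores the *pair* $(l, d)$ and needs no estimate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_H` | 100 | surviving DH pool size; used identically in the surface, the interval and the joint test (the model does not identify it from data, so it is a single configurable assumption) |
| `grid` | 100 points, 0.01–0.99 | candidate ancestral frequencies; endpoints avoid degenerate likelihoods |
| `prior_alpha`, `prior_beta` | 1/2, 1/2 | beta prior of the joint test |
| `mass` | 0.95 | aSFS interval mass |
| `outlier_fraction` | 0.05 | joint-test flagging fraction |
| `hwe_alpha` | 0.05 | mid-p threshold below which a site violates HWE |
| `max_missing` | 0.99 | per-site missing fraction above which a site is dropped (strict inequality; the default removes only essentially empty sites) |
| window width | 50 kb / 0.2 cM | physical windows for dense panels, genetic-distance windows for sparse ones |
| `min_snps` | 6 | sparse-window filter (windows with ≤ 5 SNPs removed); disabled for genetic-distance windows where low density is expected |
| `r2_max`, `window_snps`, `step` | 0.2, 50, 5 | LD pruning of control pools; the r² threshold is the analysis choice, window and step are conventional pruning defaults |
| `n_boot` | 1000 | bootstrap replicates for the heterozygosity comparison |

## Numerical choices

- All binomial, beta and choose terms are evaluated in log space with
  log-gamma and summed with a max-shifted log-sum-exp; `0^0 = 1` holds at
  the pool-count boundaries ($i = 0$, $i = n_H$) via the $k\log x$
  convention with $0 \cdot \log 0 = 0$.
- Likelihood ties on the grid break to the **smaller** frequency, then
  the smaller pool count, using a relative tolerance of 1e-12 so that
  exactly symmetric counts (e.g. $l/n_L = d/n_D = 1/2$) resolve
  deterministically to the grid point below 1/2.
- The "central" interval is the equal-tail construction: `s_lo` is the
  largest count with $P(S < s) < (1-\text{mass})/2$ and `s_hi` the
  smallest with $P(S > s) < (1-\text{mass})/2$; the contained mass is
  therefore always ≥ the target, which makes the aSFS test conservative
  on discrete counts. A highest-density alternative (`interval_type =
  "hpd"`) is provided; equal-tail is the default because "central" is the
  natural reading for a discrete distribution.
- The top-5% rule uses the nearest-rank quantile with *strict* exceedance,
  so ties can only shrink, never inflate, the flagged fraction.
- The exact HWE test conditions on the allele counts, ranks heterozygote
  configurations by conditional probability (two-sided) and reports the
  mid-p value: full mass of strictly more extreme configurations plus
  half the mass of equally probable ones. A site is removed only when it
  violates HWE (mid-p < α) in **every** landrace accession with data —
  the retention-vs-removal direction of the threshold is the only
  coherent reading of combining "violation" with a 0.05 cutoff.
- Per-site chromosome counts `n_L`, `n_D` use non-missing genotypes only
  and therefore vary across sites.

## The synthetic-data generator

`simulate_accession()` draws, per site independently: HWE diploid LR
genotypes at the ancestral frequency; a surviving pool of `n_H` DH lines
whose carrier probability is $p(1-s)/(1-ps)$ — the exact conditional
distribution obtained when carrier lines die with probability $s$ and
dead lines are redrawn until `n_H` survivors, so the closed form *is* the
rejection scheme, just without the loop; and a genotyped DH sample drawn
from the pool without replacement (hypergeometric). Defaults (23 LR
individuals, 58 DH lines, pool of 100, ancestral frequencies uniform on
0.05–0.95) mirror a realistic accession pair and are the conditions under
which the calibration checks in `scripts/acceptance.R` run.
`simulate_window_haplotypes()` adds a founder-haplotype block model (K
founders per window, Dirichlet frequencies) for the haplotype statistics.

What the generator does **not** emulate: linkage disequilibrium between
sites of the single-SNP simulator (sites are independent), recombination
within windows, demography or drift in the ancestral population, array
ascertainment bias, and genotyping error. Passing calibration on these
simulations therefore validates the *sampling model and its
implementation*, not robustness to LD or ascertainment in real panels;
with correlated sites the effective number of independent tests is
smaller and genome-wide outlier counts should be read accordingly.

## Design decisions on open points

- **DH haplotype counting**: each DH line contributes *one* haplotype
  string (its chromosomes are identical); LR individuals contribute two.
  Frequencies are unaffected; the $N/(N-1)$ correction in Nei's $H$ uses
  the honest sample size.
- **Missing alleles in windows**: a haplotype string containing any
  missing call is dropped whole, rather than treating "missing" as a
  fifth symbol that would invent haplotypes.
- **Window anchoring**: tiles start at coordinate 0 (`[kw, (k+1)w)`), not
  at the first SNP — deterministic and map-independent.
- **"Fixed"** requires DH frequency exactly 1 among retained strings.
- **Heterozygosity-enrichment matching frequency**:
  `frequency_match_sample()` is agnostic about which per-SNP frequency it
  bins on; the pipeline matches on the *estimated ancestral frequency*.
  Under an HWE landrace, heterozygosity is a deterministic function of
  the LR allele frequency, so matching on LR frequency would equalize the
  groups by construction and null the comparison; matching on the
  ancestral estimate compares sites with the same presumptive starting
  point, which is the recessive-exposure hypothesis actually under test.
- **Chip-specific exclusions** (off-target probes, call-rate classes) are
  not reproducible from genotypes and enter as a generic exclusion list
  (`filter_excluded()`).
- **Allele polarization for load**: the "derived" allele is the pooled
  minor (alternative) allele after harmonization — the only polarization
  available without an outgroup.
- **Command-line interface**: the exported functions, the pipeline runner
  and the acceptance script are the interface; no separate binary is
  shipped.

## Problem sizes

The test suite and acceptance script run simulations of 2,000–10,000
sites and up to 100 windows, with 500-site replicates for
estimator-convergence checks and 1,000 random configurations for
normalization checks — sizes chosen so each statistical property is
resolvable well beyond its Monte-Carlo noise while the whole suite stays
interactive.

## Known limitations

- `n_H` is assumed, not estimated; misspecifying it changes interval
  widths (larger pools narrow the pool-survival stage's variance).
- The aSFS interval is built at a point estimate of the ancestral
  frequency and does not propagate its uncertainty; coverage is
  guaranteed only when the true frequency is used, which is what the
  calibration check verifies, and is conservative-by-construction
  otherwise only insofar as the discrete interval overshoots.
- The joint test's top-5% rule is relative within an accession: it always
  flags ~5% of sites whether or not selection occurred; interpretation
  rests on overlap across accessions and enrichment analyses.
- Exact-HWE filtering and the rank test use base R (`wilcox.test`,
  `t.test`) conventions for ties and approximations.
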