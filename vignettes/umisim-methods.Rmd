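---
title: "Simulating single-molecule barcoded PCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating single-molecule barcoded PCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

When a library is amplified by PCR and sequenced, the number of reads
attributed to a transcript is routinely used as a measure of its abundance.
Unique molecular identifiers (UMIs) — short random nucleotide barcodes
ligated to each template molecule before amplification — make the
distortions of that measure visible: all reads carrying one barcode descend
from one template, so the *barcode family size* records how strongly that
single molecule was amplified and sampled.  Experimentally these family
sizes are wildly heterogeneous, spanning two orders of magnitude even for a
monoclonal template under constant bulk conditions.  `umisim` implements a
complete in-silico counterpart of the barcoded workflow — labelling, PCR as
a branching process, subsampling into a sequencer, per-base error — plus
the statistics needed to say *which* sources of stochasticity can and
cannot explain an observed family-size distribution.

# The pipeline and its stages

One simulated experiment is

```{r}
library(umisim)
pool <- make_pool(12)                                  # 4^12 barcodes
lab  <- label_molecules(pool, 1e4, seed = 1)           # clash possible
amp  <- amplify(lab, model_config(6, cycles = 25,
                                  eff_mean = 0.3, eff_sd = 0.3), seed = 2)
fam  <- family_size_distribution(subsample(amp, ratio = 1, seed = 3))
fit_ztp_mle(fam)
```

Each stage takes its own seed; a fixed (seed, configuration) pair
reproduces results exactly, and `run_experiment()` derives one seed per
stage per repeat from a single base seed so stages can be varied
independently.

## Labelling and barcode clash

Barcodes are drawn from the pool's weight distribution **with
replacement**: two templates can receive the same barcode (a *clash*), and
the simulator never prevents it, because clash is precisely one of the
artefacts one wants to quantify.  For a uniform pool of $N$ barcodes and
$n$ molecules the probability that no clash occurs is the birthday product
$\prod_{i=0}^{n-1}(1 - i/N)$, and the expected fraction of uniquely
barcoded molecules is $((N-1)/N)^{n-1}$ — for $n = 10^6$ and $N = 10^7$
about $0.905$, the regime of a 12-mer UMI protocol.  `prob_no_clash()`
computes the exact product (with the classical $e^{-n(n-1)/2N}$
approximation available under `method = "approx"`), and `clash_scan()`
tabulates both over a design grid.

Barcodes are integer ids; nucleotide strings are materialised only on
demand (`barcode_seq()`, id expanded in base 4 over A/C/G/T), so pools of
$4^{12} \approx 1.7\times 10^7$ barcodes carry no per-string memory cost.

Synthesised pools are not perfectly uniform.  `make_pool()` therefore also
draws per-barcode weights from a normal distribution restricted to positive
values (draws $\le 0$ are rejected and redrawn, so no probability mass
accumulates at zero), from a lognormal, or from an *empirical mixture* of
barcode classes — the representation in which an inferred pool structure
(below) can be fed back into the simulator.

## Six branching-process models of PCR

PCR is a Galton–Watson branching process: in each cycle each molecule is
either replicated (offspring 2) or not (offspring 1).  The models differ in
where the replication probability comes from:

| model | per-cycle replication probability | extra parameters |
|---|---|---|
| 1 | constant $e$ | — |
| 2 | constant $e$; a failed molecule degrades w.p. $d$ | $d$ |
| 3 | $p_t = \min(1, R/M_t)$, fixed resource $R$ | $R$ (multiple of $M_0$) |
| 4 | as 3, resource consumed: $R_{t+1} = \max(0, R_t - \delta s_t)$ | $\delta$ |
| 5 | fresh draw per molecule per cycle from $N(\mu,\sigma)$ on $[0,1]$ | $\mu, \sigma$ |
| 6 | one draw per initial template, inherited by all descendants | $\mu, \sigma$ |

$M_t$ is the population at the start of cycle $t$ and $s_t$ the number of
successful replications.  Expected growth under Model 1 is
$(1+e)^c$ after $c$ cycles (`expected_final_copies()`); qPCR-measured
efficiencies of real reactions sit around 0.8–0.9, and 25 cycles at
$e \in \{0.85, 0.9, 0.95\}$ are the canonical settings for looking at the
copy-number distribution.  Its characteristic feature is a shoulder at
$(1+e)^{c-1}$ — half the average — carrying a fraction $\approx 1-e$ of
lineages: the molecules that missed the first cycle, the only cycle whose
failure is never averaged away.

Two wording-level ambiguities had to be resolved:

* **Model 3.** The verbal definition of the resource models can be read as
  $M_t/R$, which is not a probability; the accompanying description —
  efficiency *decreases once the population exceeds the capacity* — pins
  the intended quantity down to $p_t = \min(1, R/M_t)$, which is what is
  implemented.  Growth then saturates at $R$ new molecules per cycle.
* **Model 5.** We draw one efficiency per molecule per cycle (rather than
  one shared draw per cycle).  Because the draws are i.i.d. across
  molecules, the number of successes in a lineage of $m$ molecules is
  *exactly* Binomial($m$, $\bar e$) with $\bar e$ the truncated-normal
  mean — Model 5 is marginally indistinguishable from Model 1 at matched
  mean efficiency.  This is deliberately surfaced as a tested property, not
  hidden: per-cycle, per-molecule variation that is not inherited cannot
  generate excess family-size dispersion.

Model 6 is the interesting one: the efficiency is a heritable property of
the lineage, so the final copy number is $\approx (1+e_i)^c$ with $e_i$
random across lineages — a log-scale spread that no amount of averaging
removes.  At $(\mu,\sigma) = (0.5, 0.5)$ and $c = 25$ the cross-lineage
coefficient of variation of copy numbers is (by quadrature over the
truncated normal) $2.59$, against $0.58$ for Model 1 at the matched mean —
a ratio of $4.5$.

Efficiencies for Models 5–6 are drawn from the normal *truncated* to
$[0,1]$ by inversion of the conditional CDF (`rtrunc01_norm()`): exactly
the truncated law, no atoms at the boundaries, one uniform per draw.

## Count path and sequence path

With `error_rate = 0` no two molecules of a lineage can differ, so
amplification runs on copy *counts*: one binomial draw per lineage per
cycle, making $10^5$ lineages over 25 cycles essentially free.  With a
positive per-base error rate every molecule's sequence is tracked;
replication copies the parent and mutates the copy (`mutate_copy()`: each
position substituted independently, a substituted position taking one of
the three other bases uniformly).  The two paths are distributionally
identical in copy numbers (`amplify(..., path = "sequence")` forces the
slow path to let the test suite verify this).  The count path aborts above
a configurable population cap (default $10^{12}$; the sequence path's
default cap is $10^7$ molecules) — inherited-efficiency runs at 25 cycles
genuinely reach $5\times 10^9$ molecules, which is why the cap sits above
that and why per-lineage copy numbers are held below $2^{31}$.

## Subsampling and the zero-truncated Poisson law

Loading the sequencer draws `size` molecules uniformly **without
replacement** (each physical molecule can be loaded once); over lineage
counts this is a multivariate hypergeometric draw.  It is implemented by
sampling distinct molecule *positions* in $1..M$ as exact doubles and
mapping them to lineages through the cumulative copy vector — equivalent
to the hypergeometric chain but valid for totals beyond the 32-bit range,
which the inherited-efficiency conditions require.

Lineages with zero sampled molecules are invisible, so under uniform
amplification the observed family sizes follow a *zero-truncated* Poisson
(`ztp_pmf()`), with rate equal to the sample ratio $r = S/n$ when every
lineage holds equally many copies:
$$P(k) = \frac{\lambda^k e^{-\lambda}}{k!\,(1 - e^{-\lambda})},\qquad k \ge 1 .$$
The Poisson is itself an approximation to the underlying
binomial/hypergeometric draw; it is excellent whenever $S$ is small
relative to the amplified total (the regimes used in the tests keep the
per-molecule inclusion probability below $10^{-2}$).  `ztp_moments()`
provides the closed-form mean $\lambda/(1-e^{-\lambda})$, variance and CV
used in the CV comparisons.

## Fitting and goodness of fit

`fit_ztp_mle()` maximises the ZTP likelihood by bracketed 1-D optimisation
(tolerance $10^{-10}$); the optimum coincides with the solution of the
moment equation $\lambda/(1-e^{-\lambda}) = \bar k$, and the test suite
checks both routes agree to $10^{-6}$.  An all-singletons histogram drives
$\hat\lambda$ to the lower boundary (the ZTP degenerates to a point mass at
1 as $\lambda \to 0$); such fits are flagged, not silently returned.

`chi_squared_gof()` compares observed to expected counts.  The binning rule
is stated explicitly because it is a genuine free choice: the right tail is
pooled into a single $k \ge K$ bin chosen so the tail expects at least 5
counts, any remaining thin bins are pooled from the left, and the degrees
of freedom are `bins − 1 − #fitted parameters`.  Fewer than three bins
after pooling raises an error rather than a meaningless p-value.  On true
ZTP data the test holds its nominal level (checked over 100 replicate
fits); on inherited-efficiency output it rejects with p-values
indistinguishable from zero, the simulator's counterpart of the
experimental rejection.

`fit_zt_mixed_poisson()` fits the zero-truncated $K$-component Poisson
mixture
$$P(k) = \frac{\sum_j w_j\,\mathrm{Pois}(k;\lambda_j)}{1 - \sum_j w_j e^{-\lambda_j}}$$
to barcode-labelling-event counts, maximising the likelihood over an
unconstrained parameterisation (log rates, softmax weights) with 10 random
restarts (Nelder–Mead, relative tolerance $10^{-10}$; the one-component
case uses exact bracketed optimisation), selecting $K$ by AIC over
$1..K_{max}=3$ when not fixed.  `infer_pool_structure()` reads the fit as a
description of the barcode pool — component weight = fraction of the pool,
rate = relative labelling propensity — and emits a mixture specification
that `make_pool()` accepts, closing the loop: a pool built from the
inferred structure, relabelled at the estimated molecule count, reproduces
the fitted event histogram (verified by chi-squared non-rejection).  The
number of components behind any given empirical fit, and the exact
fit-to-pool mapping, are not uniquely determined by the data; the mapping
above is one faithful reading and is the documented contract.

## Sequencing error and outputs

Sequencing applies the same substitution model as replication, at its own
rate ($10^{-4}$ per base is the reference setting: 0.025 expected errors on
a 250-base read).  Reads can be grouped by true lineage (ground truth) or
by observed barcode, in which mode clash merges families and
barcode-position errors split them, as they would experimentally.  FASTQ
is written through `Biostrings` with constant placeholder qualities
(Phred 40): quality-score modelling is out of scope.  Family-size tables
travel as 2-column TSV, fits as JSON; every `run_experiment()` output
directory carries a JSON sidecar of the producing configuration.

# What the generator does and does not emulate

The defaults are the reference study conditions: 12-mer barcodes
($1.7\times10^7$ barcode space), labelling $10^4$–$10^6$ molecules,
25 cycles, efficiencies around 0.9 (constant) or truncated-normal with low
mean and large spread (inherited), sample ratios 0.5–2, sequencing error
$10^{-4}$.  Repeat counts follow the reference protocol of 10 repeated
simulations aggregated as mean ± sd per family-size bin.  The test suite
and examples run the same pipeline at reduced sizes ($10^3$–$10^5$
lineages, 6–25 cycles) chosen so the whole suite completes in well under a
minute while leaving Monte-Carlo standard errors far below the tested
tolerances.

Passing tests show that the *simulator* reproduces its own analytic laws
and the qualitative phenomenology of barcoded PCR: they do not show that
any particular real library behaves like Model 6, and several known
features of real data are deliberately absent — primer-sequence effects,
secondary structure, strand bookkeeping, chimeras, length-dependent
amplification, flow-cell spatial effects, and quality-dependent error.
Experimental family-size distributions from real sequencing runs are not
reproducible from this package and are represented only by the two
qualitative regimes (sampling-only versus inherited efficiency).

One quantitative caveat surfaced by the simulations themselves: sampling
*dilutes* amplification heterogeneity.  At $(\mu,\sigma)=(0.3,0.3)$,
$c=25$, the copy-number CV exceeds the matched Model 1 baseline roughly
sevenfold, but after sampling $10^4$ reads from the $\sim 5\times10^9$
amplified molecules the observed family-size CV exceeds the baseline by
a factor of about 2.6 — still unambiguous (and the chi-squared test
rejects the Poisson at machine-zero p-values), but far smaller than the
pre-sampling contrast.  CV comparisons between models are therefore most
informative when quoted at matched sample ratios.

# Numerical and degenerate-input choices

* Ranks in `compare_runs()` are ascending and *dense*: tied sizes share a
  rank and no gap follows a tie.
* The CV uses the population standard deviation (denominator $n$) by
  default, switchable to the sample form.
* `prob_no_clash()` accumulates `log1p` terms, stable to $n = 10^6$ and
  beyond; `n > N` returns exactly 0.
* Model 2 is the only model whose trajectories can decrease (degradation
  applies only to molecules that failed to replicate in that cycle, and a
  lineage can go extinct); all other models are non-decreasing, and the
  tests assert exactly that.
* `sd = 0` efficiency distributions are honoured exactly (no degenerate
  normal draws), which is what makes the Model 5/6 → Model 1 collapse
  testable bit-for-bit in expectation.
* Every stochastic function accepts `seed = NULL` (use the session RNG) or
  an integer; seeds are applied with `withr::with_seed`, so library calls
  never disturb the caller's RNG state.
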