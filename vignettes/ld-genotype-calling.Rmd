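---
title: "LD-aware genotype calling: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-aware genotype calling: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldgeno)
```

## The inference problem

A low-coverage shotgun experiment yields, at each biallelic SNP locus
$i \in \{1,\dots,n\}$, a possibly empty set of read observations
$\mathbf r_i$, each an allele call in $\{0,1\}$ with a Phred quality $q$
and optionally a mapping confidence $m(r) \in (0,1]$. The goal is the
diploid genotype $g_i = h_i + h'_i \in \{0,1,2\}$, the sum of the
maternal and paternal alleles. At 4–6× mean coverage a heterozygous locus
frequently shows only one of its two alleles, so per-locus evidence alone
systematically undercalls heterozygotes; linkage disequilibrium (LD) in
the population, summarized by a phased reference panel, supplies the
missing information.

## Read-level likelihoods

For a read $r$ covering locus $i$ with error probability
$\varepsilon = \min(10^{-q/10}, 0.5)$:

* homozygous genotype matching the read allele: factor $1-\varepsilon$;
* homozygous mismatching: factor $\varepsilon$;
* heterozygous: either chromosome is sampled with probability $1/2$, and
  the correct-call and error paths sum to
  $(1-\varepsilon)/2 + \varepsilon/2 = 1/2$ exactly, for every
  $\varepsilon$.

Each factor is raised to the power $m(r)$, which interprets a read mapped
with confidence $m$ as an $m$-fraction of a confidently mapped read (the
weighted products are no longer probabilities, but normalization at the
posterior stage absorbs this). The per-locus triples
$L_i(g) = P(\mathbf r_i \mid g)$ are accumulated in log space in one
$O(m)$ pass (`genotype_likelihoods()`); an uncovered locus has the
neutral triple $(1,1,1)$. The $\varepsilon$ cap at $0.5$ reflects that an
allele call wrong more than half the time is uninformative, and prevents
$q=0$ observations from carrying negative information.

## The founder-haplotype chains

Each parental population is modelled by a left-to-right HMM with $K$
hidden *founder* states: $P(f_1)$, per-interval transitions
$P(f_{i+1}\mid f_i)$ and per-locus allele emissions $P(h_i \mid f_i)$.
An observed haplotype is thus a mosaic of $K$ ancestral haplotypes with
occasional switches — the standard copying-model picture of historical
recombination. `hap_hmm()` estimates the parameters from the panel by
Baum–Welch, treating each panel haplotype as an independent emission
sequence.

Choices the estimator exposes, with defaults:

* **`K = 7`** founders. More founders fit more local haplotype diversity
  at quadratic-to-cubic cost in the caller; 7 is the package default and
  the value used in all shipped experiments.
* **Initialization** (`seed`): Dirichlet(1)-perturbed uniform rows —
  the average of the uniform vector and a normalized vector of iid
  exponentials. Symmetric starts are EM fixed points; the perturbation
  breaks the symmetry reproducibly, and identical panel + configuration +
  seed gives bit-identical fits.
* **Stopping** (`max_iter = 100`, `tol = 1e-6`): stop when the
  log-likelihood gain per iteration falls below `tol`. EM guarantees the
  trace is non-decreasing (asserted in the tests to within $10^{-8}$).
* **`pseudocount = 1e-6`** added to every expected count before
  renormalization. Without it the M-step can drive an emission exactly to
  zero, after which a single discordant read at that locus would zero out
  the entire forward pass. The value is small enough not to perturb
  well-supported estimates.
* **`n_restarts = 1`**: EM is only locally convergent; restarts with
  best-final-likelihood selection are available but off by default since
  the downstream calling accuracy proved insensitive to the local optimum
  reached.

When only one panel is available the same fitted model serves as both the
maternal and paternal chain (`paternal` defaults to `maternal`
throughout).

## The factorial caller

The two chains are coupled only through the data: at locus $i$ the pair
$(f, f')$ emits $(h, h')$ with
$\gamma_i(f,f',g) = \sum_{h+h'=g} P(h\mid f)\,P(h'\mid f')$, and the
joint emission of the read set is
$\varphi_i(f,f') = \sum_g L_i(g)\,\gamma_i(f,f',g)$. A forward–backward
pass over the $K \times K'$ joint state computes the marginals
$P(g_i \mid \mathbf r)$; the called genotype is the per-locus argmax
(posterior decoding). The exact joint-MAP multilocus genotype is NP-hard,
so no Viterbi-style decoding is attempted.

Numerical and algorithmic choices:

* **Two-stage marginalization.** The propagation
  $\sum_{f,f'} \alpha(f,f')\,T(f,k)\,T'(f',l)$ is evaluated as two
  successive matrix products, first over $f$ then over $f'$, costing
  $O(K^2K' + KK'^2)$ per locus instead of $O(K^2K'^2)$ — the $O(m+nK^3)$
  overall runtime. A naive double-sum engine
  (`forward_backward(..., engine = "naive")`) is kept solely as a
  cross-check; the two agree entry-wise to $10^{-12}$ relative in the
  tests.
* **Scaling, not log space.** Each forward slice is normalized to sum
  to 1 and the per-locus constants are accumulated into the total
  log-likelihood; the backward pass reuses the same constants, making
  $\sum_{f,f'}\alpha_i\beta_i = 1$ at every locus — an identity the tests
  assert. Scaling keeps the inner loops as dense matrix products, which
  log-space tables would forfeit. Likelihood triples are additionally
  rescaled per locus by their maximum (with the log of the constant
  re-added to the total), so arbitrarily deep pileups cannot underflow.
* **Emission-once convention.** The forward table at locus $i$ includes
  the locus-$i$ emission; the backward table covers loci $i{+}1,\dots,n$;
  the marginal at $i$ therefore combines the *pre-emission* forward mass
  with the per-genotype split $L_i(g)\gamma_i(\cdot,\cdot,g)$ and the
  backward mass, counting the emission exactly once. The convention is
  internal: its correctness is established against
  `brute_force_posteriors()`, which enumerates all $4^n$ haplotype pairs
  and is the normative definition of the model. The shipped tests verify
  agreement to $10^{-9}$ absolute on over a hundred random instances with
  $n \le 6$, $K, K' \le 3$.
* **Ties** in the posterior argmax are broken toward the genotype with
  the larger data-free model prior, then toward the smaller genotype —
  deterministic by construction.
* **Degenerate inputs.** A locus with no reads returns the model-implied
  genotype prior (verified analytically and against the oracle). A read
  set with zero probability under zero-pseudocount emissions aborts with
  a message pointing at the training pseudocount rather than returning
  NaNs.
* **No-call thresholding** (`apply_no_call_threshold()`): a locus is left
  uncalled when its maximum posterior is below $t$; the call rate is
  non-increasing in $t$ by construction.

With $K = K' = 1$ the factorial model factorizes across loci and the
caller provably reduces to the single-SNP Bayesian caller under the
model-implied prior — a closed-form identity the tests check numerically.

## Baselines

`call_single_snp()` applies Bayes' rule per locus with a panel-derived
prior. The prior estimator (`genotype_prior()`) defaults to Hardy–
Weinberg from smoothed allele frequencies,
$p_i = (c_1 + s)/(N + 2s)$ with pseudocount $s = 1$, because a panel is a
haplotype list and HWE is the natural two-parameter reduction; direct
genotype counting over consecutive haplotype pairs is available as
`mode = "count"` for panels whose row pairing is meaningful. The
pseudocount guarantees no genotype has a hard zero prior that would veto
read evidence.

`call_binomial()` reconstructs the classical allele-count recipe: call
heterozygous when both alleles are covered at least once and a two-sided
exact binomial test against 0.5 does not reject at $\alpha = 0.01$,
otherwise the majority homozygote. The historical variants differ in
test sidedness and error-rate adjustment; the implemented form is
documented here rather than asserted to be identical to any one of them,
and its defining weakness — a minimum-coverage requirement that forfeits
every locus where one allele went unsampled — is shared by all variants.

## What the simulator emulates — and what it does not

`sim_panel()` generates founders as Bernoulli(½) haplotypes and panel
members as mosaics with per-step switch probability 0.01 and per-allele
flip probability 0.005 — values chosen to give realistic block structure
(mean block length ~100 SNPs) and panel noise at desk scale.
`sim_individual()` samples parental haplotypes independently from the
*fitted* models (random mating); `sim_reads()` draws per-locus coverage
as Poisson($\lambda$), the standard shotgun idealization of the
reported mean mapped coverage, with constant Phred-20 qualities by
default (real quality distributions are instrument-specific and the
package accepts any discrete distribution). The `ref_bias` knob makes a
heterozygous-site read sample the reference chromosome with probability
$\ne 0.5$, reproducing the mechanism by which color-space mapping bias
inflates reference-allele coverage ratios; `downsample_reads()` thins
pileups to nested m/16 … m/2 subsets under one seed.

The simulator does **not** emulate: sequence-level errors (indels,
context-dependent miscalls), mapping artifacts beyond the single bias
knob, duplicated reads, population structure between the individual and
the panel, or panel phasing errors beyond iid flips. Passing tests
therefore demonstrate correctness of the inference machinery and the
expected qualitative behaviour (LD gain concentrated in heterozygotes at
low coverage, graceful degradation under downsampling, bias-induced het
loss) — not calibrated accuracy on any real instrument.

## Study sizes used in the shipped tests

The standard fixture is a 120-haplotype × 1000-SNP panel from 10
founders, one simulated individual, and Phred-20 reads at 6× and 20×
mean coverage; oracle comparisons run at $n \le 6$, $K \le 3$ where
$4^n$ enumeration is exact and fast, and the recurrence cross-check at
$n = 20$, $K = K' = 5$. These sizes were chosen so the full suite
exercises every code path in well under a minute while keeping Monte
Carlo standard errors an order of magnitude below the asserted margins.

## Known limitations

* Posterior decoding maximizes per-locus marginals; the returned vector
  need not be the jointly most probable multilocus genotype (that problem
  is NP-hard) and can even be jointly inconsistent with any high-probability
  haplotype pair.
* Haplotype phasing of the sequenced individual is not attempted.
* Only biallelic SNPs on autosomes are supported; reads carrying
  non-panel alleles are dropped at load time, so novel-variant discovery
  must happen upstream.
* The panel is assumed to represent the individual's population; model
  misspecification (admixture, rare haplotypes absent from the panel)
  degrades the LD gain in ways the simulator does not model.
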