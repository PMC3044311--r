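# ldgeno — LD-aware genotype calling from low-coverage sequencing

Low-coverage shotgun sequencing leaves many SNP loci covered by only one or
two reads — or none at all — so callers that look at each locus in isolation
cannot reliably distinguish a heterozygote from a homozygote whose second
allele simply went unsampled. Yet alleles at nearby SNPs are strongly
correlated (linkage disequilibrium), and phased reference panels such as
Hapmap carry that correlation structure. `ldgeno` is for researchers who
want to call diploid genotypes from per-SNP read pileups while borrowing
strength across loci from such a panel.

## The model

Each parental haplotype is modelled by a **founder-haplotype HMM**: a
left-to-right HMM with *K* hidden founder states whose per-locus emissions
are the 0/1 alleles, so every observed haplotype is a recombination mosaic
of *K* ancestral haplotypes. Its parameters P(f₁), P(f_{i+1}|f_i) and
P(h_i|f_i) are estimated from the phased panel by Baum–Welch
(`hap_hmm()`, default K = 7).

Two such chains — maternal *M* and paternal *M′*, independent by random
mating — are coupled in a **hierarchical factorial HMM**: at locus *i* the
founder pair (f, f′) emits alleles (h, h′), the genotype is
g_i = h_i + h′_i ∈ {0, 1, 2}, and g_i generates the reads covering the
locus. Per-read likelihood factors are (1 − ε) for the matching homozygote,
ε for the mismatching one, and exactly ½ for a heterozygote, with
ε = 10^(−q/10) from the Phred score q and each factor raised to the read's
mapping confidence m(r).

Calling is by **posterior decoding**: a scaled forward–backward pass over
the joint founder state computes P(g_i | all reads) for every locus in
O(m + nK³) time (the exact joint-MAP genotype is NP-hard), and the
maximum-posterior genotype is called, optionally leaving loci with low
posterior uncalled. Uncovered loci are retained and imputed through LD —
that is the point of the method. LD-oblivious baselines
(`call_single_snp()`, a per-locus Bayesian caller with panel-derived
priors; `call_binomial()`, an exact-binomial allele-count test) are
included for comparison, together with a seeded mosaic-haplotype simulator
and a concordance harness.

## Worked example

```r
library(ldgeno)

panel <- sim_panel(n_snps = 200, n_haplotypes = 60, n_founders = 5, seed = 1)
fit   <- hap_hmm(panel, K = 5, seed = 1)
ind   <- sim_individual(fit, seed = 2)            # truth: h, h', g = h + h'
reads <- sim_reads(ind$g, mean_coverage = 4, phred_dist = 20, seed = 3)
reads
#> Read pileup: 774 observations over 200 loci (mean coverage 3.87, 3 uncovered)

calls <- call_ld(reads, fit)                      # HF-HMM posterior decoding
concordance(calls, ind$g)
#> Concordance over 200 loci (call rate 1.0000)
#>   overall 0.9900   homozygous 0.9787   heterozygous 1.0000

concordance(call_single_snp(reads, genotype_prior(panel)), ind$g)
#> Concordance over 200 loci (call rate 1.0000)
#>   overall 0.8750   homozygous 0.9574   heterozygous 0.8019

tradeoff_curve(calls, ind$g, c(0, 0.9, 0.99))
#>   threshold call_rate overall homozygous heterozygous
#> 1      0.00     1.000    0.99  0.9787234            1
#> 2      0.90     0.955    1.00  1.0000000            1
#> 3      0.99     0.905    1.00  1.0000000            1
```

At 4× mean coverage the LD-aware caller reaches 99% overall concordance
with the simulated truth where the single-SNP Bayesian caller manages
87.5% — the gap concentrated in heterozygotes, exactly where single-locus
evidence is weakest. Raising the no-call threshold trades a few percent of
call rate for perfect concordance on the retained calls.

Founder models round-trip through JSON (`write_hap_hmm()` /
`read_hap_hmm()`); panels load from hap/legend files or phased VCF; pileups
and calls are plain TSV. A small-instance enumeration oracle
(`brute_force_posteriors()`) computes the exact posteriors by summing over
all 4ⁿ haplotype pairs and backs the test suite.

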