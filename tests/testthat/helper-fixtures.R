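# Shared generators and the memoized standard simulation fixture.

# Random valid founder HMM with arbitrary (non-trained) parameters.
rand_hmm <- function(K, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  norm_rows <- function(m) m / rowSums(m)
  init <- as.vector(norm_rows(matrix(runif(K), 1)))
  trans <- array(0, c(K, K, max(n - 1, 0)))
  if (n > 1) for (i in 1:(n - 1))
    trans[, , i] <- norm_rows(matrix(runif(K * K), K))
  emis <- array(0, c(K, 2, n))
  for (i in 1:n) emis[, , i] <- norm_rows(matrix(runif(K * 2), K))
  hap_hmm_model(init, trans, emis)
}

# Random pileup with Poisson coverage and mixed qualities.
rand_pileup <- function(n, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- rpois(n, lambda)
  pileup_data(locus = rep(seq_len(n), nr),
              allele = rbinom(sum(nr), 1, 0.5),
              phred = sample(c(10, 20, 30), sum(nr), replace = TRUE),
              n = n)
}

# Standard fixture: mosaic panel of 120 haplotypes over 1000 SNPs from 10
# founders (switch 0.01, flip 0.005, seed 1); K = 7 models; one simulated
# individual with reads at 6x and 20x mean coverage, Phred 20 (seed 2).
# Computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

standard_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  panel <- sim_panel(n_snps = 1000, n_haplotypes = 120, n_founders = 10,
                     switch_prob = 0.01, flip_prob = 0.005, seed = 1)
  fit <- hap_hmm(panel, K = 7, seed = 1)
  ind <- sim_individual(fit, seed = 2)
  reads6 <- sim_reads(ind$g, mean_coverage = 6, phred_dist = 20, seed = 2)
  reads20 <- sim_reads(ind$g, mean_coverage = 20, phred_dist = 20, seed = 2)
  fx <- list(panel = panel, fit = fit, ind = ind, reads6 = reads6,
             reads20 = reads20, prior = genotype_prior(panel))
  .fixture_cache$fx <- fx
  fx
}
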