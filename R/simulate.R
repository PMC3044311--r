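#' Simulate a mosaic-haplotype reference panel
#'
#' Generative mirror of the founder model: `n_founders` random founder
#' haplotypes are drawn, and each panel haplotype copies a founder,
#' switching to a uniformly chosen founder with probability
#' `switch_prob` at each locus step (historical recombination) and
#' flipping each copied allele with probability `flip_prob` (mutation /
#' genotyping error in the panel).
#'
#' @param n_snps number of SNP loci.
#' @param n_haplotypes number of panel haplotypes.
#' @param n_founders number of true founders.
#' @param switch_prob per-step founder switch probability.
#' @param flip_prob per-allele flip probability.
#' @param seed RNG seed; fixed seed gives a bit-identical panel.
#' @return a [haplotype_panel] with attributes `founders` (the founder
#'   matrix) and `founder_paths` (which founder each haplotype copied at
#'   each locus).
#' @export
sim_panel <- function(n_snps, n_haplotypes, n_founders = 10,
                      switch_prob = 0.01, flip_prob = 0.005, seed = NULL) {
  stopifnot(n_snps >= 1, n_haplotypes >= 2, n_founders >= 1,
            switch_prob >= 0, switch_prob <= 1,
            flip_prob >= 0, flip_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_founders > 2^n_snps)
    warning("more founders than distinct haplotypes exist")
  founders <- matrix(as.integer(stats::runif(n_founders * n_snps) < 0.5),
                     n_founders, n_snps)
  paths <- matrix(0L, n_haplotypes, n_snps)
  paths[, 1] <- sample.int(n_founders, n_haplotypes, replace = TRUE)
  if (n_snps > 1L) for (i in 2:n_snps) {
    switch <- stats::runif(n_haplotypes) < switch_prob
    paths[, i] <- ifelse(switch,
                         sample.int(n_founders, n_haplotypes, replace = TRUE),
                         paths[, i - 1L])
  }
  hap <- matrix(founders[cbind(as.vector(paths),
                               rep(seq_len(n_snps), each = n_haplotypes))],
                n_haplotypes, n_snps)
  flip <- matrix(stats::runif(n_haplotypes * n_snps) < flip_prob,
                 n_haplotypes, n_snps)
  hap[flip] <- 1L - hap[flip]
  p <- haplotype_panel(hap)
  attr(p, "founders") <- founders
  attr(p, "founder_paths") <- paths
  p
}

#' Simulate a diploid individual from fitted parental models
#'
#' Draws the maternal haplotype from `maternal` and the paternal one
#' independently from `paternal` (random mating); the true genotype is
#' their sum.
#'
#' @param maternal,paternal [hap_hmm] models (paternal defaults to
#'   maternal).
#' @param seed RNG seed.
#' @return list with 0/1 vectors `h_m`, `h_p` and genotype vector `g`
#'   in \{0, 1, 2\}.
#' @export
sim_individual <- function(maternal, paternal = maternal, seed = NULL) {
  .check_models(maternal, paternal)
  if (!is.null(seed)) set.seed(seed)
  h_m <- as.vector(simulate(maternal, nsim = 1))
  h_p <- as.vector(simulate(paternal, nsim = 1))
  list(h_m = h_m, h_p = h_p, g = h_m + h_p)
}

#' Simulate shotgun read observations over known genotypes
#'
#' Per-locus coverage is Poisson(`mean_coverage`). Each read samples a
#' chromosome: at homozygous loci the true allele is fixed; at
#' heterozygous loci the read carries allele 0 with probability
#' `ref_bias` (0.5 = unbiased sequencing; larger values emulate
#' reference-allele mapping bias). The reported allele then flips with
#' the error probability implied by the read's Phred score, drawn from
#' `phred_dist`.
#'
#' @param g true genotype vector in \{0, 1, 2\}.
#' @param mean_coverage Poisson mean coverage per locus.
#' @param phred_dist either a single Phred value (default 20) or a
#'   two-column matrix / data.frame of (phred, probability) defining a
#'   discrete quality distribution.
#' @param ref_bias probability that a read at a heterozygous locus
#'   samples the allele-0 chromosome.
#' @param map_conf mapping confidence attached to every read.
#' @param seed RNG seed.
#' @return a [pileup_data] object over `length(g)` loci.
#' @export
sim_reads <- function(g, mean_coverage = 6, phred_dist = 20,
                      ref_bias = 0.5, map_conf = 1, seed = NULL) {
  stopifnot(all(g %in% 0:2), mean_coverage >= 0,
            ref_bias >= 0, ref_bias <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(g)
  cov <- stats::rpois(n, mean_coverage)
  locus <- rep(seq_len(n), cov)
  m <- length(locus)
  gl <- g[locus]
  true_allele <- integer(m)
  true_allele[gl == 2L] <- 1L
  het <- gl == 1L
  true_allele[het] <- as.integer(stats::runif(sum(het)) >= ref_bias)
  if (is.null(dim(phred_dist))) {
    q <- if (length(phred_dist) == 1L) rep(phred_dist, m)
         else sample(phred_dist, m, replace = TRUE)
  } else {
    pd <- as.matrix(phred_dist)
    q <- sample(pd[, 1], m, replace = TRUE, prob = pd[, 2])
  }
  eps <- phred_to_error(q)
  err <- stats::runif(m) < eps
  obs <- ifelse(err, 1L - true_allele, true_allele)
  pileup_data(locus = locus, allele = obs, phred = q, map_conf = map_conf,
              n = n)
}

#' Randomly downsample a pileup
#'
#' `mode = "exact"` (default) keeps the first `floor(m * fraction)`
#' observations of a seeded random permutation, so calls with the same
#' seed and increasing fractions yield nested subsets
#' (m/16 within m/8 within ...). `mode = "bernoulli"` keeps each
#' observation independently with probability `fraction`.
#'
#' @param reads a [pileup_data] object.
#' @param fraction fraction of observations to keep, in (0, 1].
#' @param seed RNG seed.
#' @param mode `"exact"` or `"bernoulli"`.
#' @return the downsampled [pileup_data] (same locus count).
#' @export
downsample_reads <- function(reads, fraction, seed = NULL,
                             mode = c("exact", "bernoulli")) {
  stopifnot(inherits(reads, "read_pileup"), fraction > 0, fraction <= 1)
  mode <- match.arg(mode)
  if (fraction == 1) return(reads)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(reads)
  keep <- if (mode == "exact") {
    sort(sample.int(m)[seq_len(floor(m * fraction))])
  } else {
    which(stats::runif(m) < fraction)
  }
  pileup_data(locus = reads$locus[keep], allele = reads$allele[keep],
              phred = reads$phred[keep],
              error_prob = reads$error_prob[keep],
              map_conf = reads$map_conf[keep], n = attr(reads, "n"))
}
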