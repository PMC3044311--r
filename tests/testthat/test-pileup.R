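test_that("Phred conversion follows 10^(-q/10) with the 0.5 cap", {
  expect_equal(phred_to_error(10), 0.1)
  expect_equal(phred_to_error(20), 0.01)
  expect_equal(phred_to_error(0), 0.5)   # raw 1.0 is not a valid error prob
  expect_equal(phred_to_error(3), 0.5)   # still above the cap
  expect_error(phred_to_error(-1), "nonnegative")
})

test_that("site likelihood triples match the per-read closed forms", {
  # one ref read: (1-eps, 1/2, eps)
  expect_equal(site_likelihoods(0, 0.01), c(0.99, 0.5, 0.01))
  # opposing reads multiply factor-wise
  expect_equal(site_likelihoods(c(0, 1), c(0.01, 0.01)),
               c(0.0099, 0.25, 0.0099))
  # mapping confidence exponentiates each factor
  expect_equal(site_likelihoods(0, 0.01, map_conf = 0.5),
               c(0.99^0.5, 0.5^0.5, 0.01^0.5))
  # heterozygous factor is exactly 1/2 whatever the error probability
  for (eps in c(1e-6, 0.01, 0.2, 0.5))
    expect_identical(site_likelihoods(1, eps)[2], 0.5)
})

test_that("pileup-wide likelihoods are order-invariant and neutral at uncovered loci", {
  set.seed(21)
  rd <- rand_pileup(40, lambda = 3, seed = 21)
  L <- genotype_likelihoods(rd)
  expect_equal(dim(L), c(40L, 3L))
  uncov <- setdiff(1:40, rd$locus)
  for (i in uncov) expect_equal(unname(L[i, ]), c(1, 1, 1))
  perm <- sample(nrow(rd))
  rd2 <- pileup_data(rd$locus[perm], rd$allele[perm], phred = rd$phred[perm],
                     n = 40)
  expect_equal(genotype_likelihoods(rd2), L)
  # map_conf = 1 leaves the unweighted product unchanged
  rd3 <- pileup_data(rd$locus, rd$allele, phred = rd$phred, map_conf = 1,
                     n = 40)
  expect_equal(genotype_likelihoods(rd3), L)
  # against the single-site reference for one locus
  i <- rd$locus[1]
  sel <- rd$locus == i
  expect_equal(unname(L[i, ]),
               site_likelihoods(rd$allele[sel], rd$error_prob[sel]))
})

test_that("single-SNP Bayesian calls follow eq-style posteriors", {
  # uniform prior: normalize (0.99, 0.5, 0.01) by its sum 1.5
  calls <- call_single_snp(matrix(c(0.99, 0.5, 0.01), 1), rep(1/3, 3))
  expect_equal(c(calls$p0, calls$p1, calls$p2), c(0.99, 0.5, 0.01) / 1.5)
  expect_equal(calls$genotype, 0L)
  # HWE prior with one alt read: numerators (.0025, .25, .2475), sum 0.5
  L <- matrix(site_likelihoods(1, 0.01), 1)
  calls <- call_single_snp(L, c(0.25, 0.5, 0.25))
  expect_equal(c(calls$p0, calls$p1, calls$p2), c(0.005, 0.5, 0.495))
  expect_equal(calls$genotype, 1L)
  # no reads: posterior equals the prior
  rd <- pileup_data(integer(0), integer(0), phred = numeric(0), n = 2)
  calls <- call_single_snp(rd, c(0.2, 0.5, 0.3))
  expect_equal(unname(as.matrix(calls[, c("p0", "p1", "p2")])),
               matrix(c(0.2, 0.5, 0.3), 2, 3, byrow = TRUE))
  # uniform prior: call equals argmax likelihood
  set.seed(3)
  rd <- rand_pileup(30, seed = 3)
  L <- genotype_likelihoods(rd)
  calls <- call_single_snp(rd, rep(1/3, 3))
  cov <- tabulate(rd$locus, 30) > 0
  expect_equal(calls$genotype[cov], max.col(L[cov, ]) - 1L)
  expect_true(all(abs(calls$p0 + calls$p1 + calls$p2 - 1) < 1e-9))
})

test_that("disjoint prior and likelihood support yields a warned no-call", {
  L <- matrix(c(0, 1, 0), 1)       # only het has likelihood
  expect_warning(calls <- call_single_snp(L, c(1, 0, 0)), "zero posterior")
  expect_true(is.na(calls$genotype))
})

test_that("binomial baseline calls follow the allele-count rules", {
  mk <- function(n0, n1) pileup_data(rep(1, n0 + n1),
                                     c(rep(0, n0), rep(1, n1)),
                                     phred = 20, n = 1)
  expect_equal(call_binomial(mk(5, 5))$genotype, 1L)
  expect_equal(call_binomial(mk(8, 0))$genotype, 0L)
  expect_equal(call_binomial(mk(0, 8))$genotype, 2L)
  # both alleles covered once: exact binomial p = 1 > 0.01, het
  expect_equal(call_binomial(mk(1, 1))$genotype, 1L)
  # heavily skewed counts reject toward the majority homozygote
  expect_equal(call_binomial(mk(15, 1))$genotype, 0L)
  # empty pileup: no-call
  rd <- pileup_data(integer(0), integer(0), phred = numeric(0), n = 1)
  expect_true(is.na(call_binomial(rd)$genotype))
  # min allele coverage 2 demotes singleton-support hets
  expect_equal(call_binomial(mk(6, 1), min_allele_cov = 2)$genotype, 0L)
})

test_that("pileup TSV round trip preserves observations and filters non-panel alleles", {
  loci <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                     allele0 = c("A", "C", "G"), allele1 = c("G", "T", "A"))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tallele\tphred",
               "1\t100\t0\t20", "1\t100\tG\t30", "1\t200\tT\t20",
               "1\t200\t2\t20",      # non-panel code: dropped
               "1\t300\tC\t20",      # base not among panel alleles: dropped
               "1\t999\t0\t20"),     # unknown position: dropped
             f)
  expect_message(rd <- read_pileup(f, loci), "dropped")
  expect_equal(attr(rd, "m"), 3L)
  expect_equal(rd$locus, c(1L, 1L, 2L))
  expect_equal(rd$allele, c(0L, 1L, 1L))

  write_pileup(rd, f, loci)
  rd2 <- read_pileup(f, loci)
  expect_equal(rd2$allele, rd$allele)
  expect_equal(rd2$locus, rd$locus)
  expect_equal(attr(rd2, "m"), attr(rd, "m"))
})

test_that("calls TSV round trip preserves genotypes and posteriors to 6 decimals", {
  set.seed(11)
  rd <- rand_pileup(10, seed = 11)
  calls <- call_single_snp(rd, c(0.3, 0.4, 0.3))
  calls$genotype[4] <- NA_integer_
  f <- tempfile(fileext = ".tsv")
  write_calls(calls, f)
  back <- read_calls(f)
  expect_equal(back$genotype, calls$genotype)
  expect_equal(back$p1, calls$p1, tolerance = 1e-6)
  expect_true(any(grepl("\t\\.\t", readLines(f))))  # no-call flag
})
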