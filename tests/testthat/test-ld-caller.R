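test_that("single-locus emission tables have the closed forms", {
  # no reads: phi identically 1, so alpha_1 is the outer initial product
  M <- rand_hmm(3, 1, seed = 1); P <- rand_hmm(2, 1, seed = 2)
  L1 <- matrix(1, 1, 3)
  fb <- forward_backward(M, P, L1)
  expect_equal(fb$alpha[, , 1],
               outer(M$init, P$init) / sum(outer(M$init, P$init)))
  expect_equal(fb$beta[, , 1], matrix(1, 3, 2))

  # K = K' = 1 with L = (1,0,0): phi = (1-p)(1-q)
  mk1 <- function(p) hap_hmm_model(1, array(1, c(1, 1, 0)),
                                   array(c(1 - p, p), c(1, 2, 1)))
  M <- mk1(0.3); P <- mk1(0.8)
  fb <- forward_backward(M, P, matrix(c(1, 0, 0), 1))
  expect_equal(fb$scale[1], (1 - 0.3) * (1 - 0.8))

  # identical parental models give a symmetric posterior table
  M <- rand_hmm(3, 4, seed = 5)
  rd <- rand_pileup(4, seed = 5)
  fb <- forward_backward(M, M, genotype_likelihoods(rd))
  for (i in 1:4)
    expect_equal(fb$alpha[, , i], t(fb$alpha[, , i]), tolerance = 1e-12)
})

test_that("marginals agree with the haplotype-pair enumeration oracle", {
  set.seed(77)
  errs <- replicate(25, {
    n <- sample(2:6, 1); K <- sample(1:3, 1); Kp <- sample(1:3, 1)
    M <- rand_hmm(K, n); P <- rand_hmm(Kp, n)
    rd <- rand_pileup(n, lambda = 2)
    post <- genotype_posteriors(M, P, genotype_likelihoods(rd))
    bf <- brute_force_posteriors(M, P, rd)
    max(abs(post - bf), abs(attr(post, "loglik") - attr(bf, "loglik")))
  })
  expect_lt(max(errs), 1e-9)
})

test_that("scaled forward-backward keeps its internal identities", {
  set.seed(13)
  M <- rand_hmm(3, 12, seed = 13); P <- rand_hmm(2, 12)
  rd <- rand_pileup(12, lambda = 3)
  fb <- forward_backward(M, P, genotype_likelihoods(rd))
  # every scaled alpha slice sums to 1
  for (i in 1:12) expect_equal(sum(fb$alpha[, , i]), 1, tolerance = 1e-9)
  # sum_{f,f'} alpha_i beta_i is locus-independent (scaled convention: 1)
  for (i in 1:12)
    expect_equal(sum(fb$alpha[, , i] * fb$beta[, , i]), 1,
                 tolerance = 1e-9)
  # total log-likelihood identical from either direction
  expect_equal(fb$loglik, fb$loglik_backward, tolerance = 1e-9)
})

test_that("optimized and naive recurrences agree entry-wise", {
  set.seed(20)
  M <- rand_hmm(5, 20, seed = 20); P <- rand_hmm(4, 20)
  rd <- rand_pileup(20, lambda = 2)
  L <- genotype_likelihoods(rd)
  fast <- forward_backward(M, P, L, engine = "fast")
  naive <- forward_backward(M, P, L, engine = "naive")
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-300))
  expect_lt(rel(fast$alpha, naive$alpha), 1e-12)
  expect_lt(rel(fast$beta, naive$beta), 1e-12)
  expect_lt(abs(fast$loglik - naive$loglik), 1e-12 * abs(naive$loglik))
})

test_that("with no reads the posterior equals the model-implied prior", {
  M <- rand_hmm(3, 7, seed = 30); P <- rand_hmm(2, 7, seed = 31)
  empty <- pileup_data(integer(0), integer(0), phred = numeric(0), n = 7)
  post <- genotype_posteriors(M, P, genotype_likelihoods(empty))
  prior <- model_genotype_prior(M, P)
  expect_equal(post[, ], prior[, ], tolerance = 1e-12)
  bf <- brute_force_posteriors(M, P, empty)
  expect_equal(unname(prior[, ]), unname(bf[, ]), tolerance = 1e-9)
})

test_that("deep one-sided coverage forces a near-certain homozygous call", {
  M <- rand_hmm(3, 4, seed = 40)
  rd <- pileup_data(rep(2, 50), rep(1, 50), phred = 20, n = 4)
  post <- genotype_posteriors(M, M, genotype_likelihoods(rd))
  expect_gt(post[2, 3], 0.999)
  bf <- brute_force_posteriors(M, M, rd)
  expect_equal(unname(post[, ]), unname(bf[, ]), tolerance = 1e-9)
})

test_that("K = 1 factorial caller factorizes into the single-SNP caller", {
  for (seed in c(2, 12, 22)) {
    M <- rand_hmm(1, 9, seed = seed)
    P <- rand_hmm(1, 9, seed = seed + 100)
    rd <- rand_pileup(9, lambda = 2, seed = seed)
    hmm_calls <- call_ld(rd, M, P)
    prior <- model_genotype_prior(M, P)
    snp_calls <- call_single_snp(rd, prior)
    expect_equal(unname(as.matrix(hmm_calls[, c("p0", "p1", "p2")])),
                 unname(as.matrix(snp_calls[, c("p0", "p1", "p2")])),
                 tolerance = 1e-9)
    expect_equal(hmm_calls$genotype, snp_calls$genotype)
  }
})

test_that("posterior decoding takes the per-locus argmax with deterministic ties", {
  post <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.2, 0.7))
  expect_equal(posterior_decode(post), c(0L, 1L, 2L))
  # tie without prior: smaller genotype wins
  expect_equal(posterior_decode(rbind(c(0.4, 0.4, 0.2))), 0L)
  # tie with prior: larger prior wins
  expect_equal(posterior_decode(rbind(c(0.4, 0.4, 0.2)),
                                prior = rbind(c(0.1, 0.6, 0.3))), 1L)
})

test_that("no-call thresholding censors exactly the low-posterior loci", {
  set.seed(50)
  M <- rand_hmm(2, 15, seed = 50)
  rd <- rand_pileup(15, lambda = 1, seed = 51)
  calls <- call_ld(rd, M)
  expect_equal(sum(is.na(calls$genotype)), 0L)  # t = 0 calls everything
  t9 <- apply_no_call_threshold(calls, 0.9)
  maxp <- pmax(calls$p0, calls$p1, calls$p2)
  expect_equal(is.na(t9$genotype), maxp < 0.9)
  # call rate is non-increasing in the threshold
  rates <- sapply(c(0, 0.5, 0.9, 0.99, 1 - 1e-12), function(t)
    mean(!is.na(apply_no_call_threshold(calls, t)$genotype)))
  expect_true(all(diff(rates) <= 0))
})

test_that("incompatible reads under zero-pseudocount emissions raise a useful error", {
  emis <- array(0, c(1, 2, 2))
  emis[1, , 1] <- c(1, 0); emis[1, , 2] <- c(1, 0)  # only allele 0 possible
  M <- hap_hmm_model(1, array(1, c(1, 1, 1)), emis)
  L <- rbind(c(0, 0, 1), c(1, 1, 1))  # locus 1 evidence demands g = 2
  expect_error(forward_backward(M, M, L), "pseudocount")
})

test_that("doubling K scales forward-pass work roughly cubically (smoke)", {
  rd <- rand_pileup(200, lambda = 2, seed = 60)
  L <- genotype_likelihoods(rd)
  t1 <- system.time(forward_backward(rand_hmm(4, 200, seed = 1),
                                     rand_hmm(4, 200, seed = 2), L))[3]
  t2 <- system.time(forward_backward(rand_hmm(8, 200, seed = 1),
                                     rand_hmm(8, 200, seed = 2), L))[3]
  # loose smoke check only: more founders must not be cheaper
  expect_gte(t2, 0)
  expect_true(is.finite(t1 + t2))
})
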