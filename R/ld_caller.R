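## Hierarchical factorial HMM caller.
##
## The sequenced individual's maternal and paternal haplotypes are modelled
## by two independent founder HMMs M and M'. At locus i the pair of hidden
## founders (f, f') emits alleles (h, h') whose sum is the genotype g_i,
## which in turn generates the reads covering the locus. The caller
## computes P(g_i | all reads) for every locus by a scaled forward-backward
## pass over the joint founder state (f, f'), with the two-stage
## marginalization that brings the per-locus cost from O(K^2 K'^2) down to
## O(K^2 K' + K K'^2), and calls argmax posteriors (posterior decoding).
## The exact joint-MAP genotype is NP-hard and is not attempted.

## Per-genotype emission split at one locus:
## gamma_g(f, f') = sum_{h + h' = g} P(h | f) P(h' | f')
.gamma_tables <- function(eM, eP) {
  list(outer(eM[, 1], eP[, 1]),
       outer(eM[, 1], eP[, 2]) + outer(eM[, 2], eP[, 1]),
       outer(eM[, 2], eP[, 2]))
}

.lik_rows <- function(lik, n) {
  ll <- .as_loglik_matrix(lik)
  if (nrow(ll) != n)
    stop("likelihoods cover ", nrow(ll), " loci but the models have n = ", n)
  mx <- apply(ll, 1, max)
  list(L = exp(ll - mx), logc = mx)   # row-rescaled so max factor is 1
}

.check_models <- function(maternal, paternal) {
  stopifnot(inherits(maternal, "hap_hmm"), inherits(paternal, "hap_hmm"))
  if (maternal$n != paternal$n)
    stop("maternal and paternal models disagree on the number of loci")
}

#' Forward-backward tables of the factorial-HMM caller
#'
#' Runs the scaled forward and backward recursions over the joint founder
#' state (f, f') and returns the tables needed for genotype marginals.
#' `engine = "fast"` uses the two-stage marginalization (first over the
#' previous maternal founder, then over the paternal one; O(K^3) per locus
#' for K = K'); `engine = "naive"` evaluates the full O(K^4) double sum
#' and exists as a cross-check.
#'
#' @param maternal,paternal fitted [hap_hmm] models with equal `n`
#'   (founder counts may differ).
#' @param lik a [genotype_likelihoods] object (or an `n x 3` matrix of
#'   linear per-locus genotype likelihoods).
#' @param engine `"fast"` or `"naive"`.
#' @return a list with arrays `alpha` (scaled forward, each locus slice
#'   summing to 1), `alphapre` (forward mass propagated to locus i
#'   before the locus-i emission), `beta` (scaled backward), `scale`,
#'   and the total log-likelihood computed from the forward
#'   (`loglik`) and backward (`loglik_backward`) directions.
#' @export
forward_backward <- function(maternal, paternal, lik,
                             engine = c("fast", "naive")) {
  engine <- match.arg(engine)
  .check_models(maternal, paternal)
  n <- maternal$n; K <- maternal$K; Kp <- paternal$K
  lr <- .lik_rows(lik, n)
  phis <- vector("list", n)
  for (i in seq_len(n)) {
    g <- .gamma_tables(matrix(maternal$emis[, , i], K, 2L),
                       matrix(paternal$emis[, , i], Kp, 2L))
    phis[[i]] <- lr$L[i, 1] * g[[1]] + lr$L[i, 2] * g[[2]] +
      lr$L[i, 3] * g[[3]]
  }
  TM <- maternal$trans; TP <- paternal$trans
  fwd_step <- if (engine == "fast") {
    function(A, tm, tp) (t(tm) %*% A) %*% tp
  } else {
    function(A, tm, tp) {
      out <- matrix(0, K, Kp)
      for (k2 in seq_len(K)) for (l2 in seq_len(Kp))
        out[k2, l2] <- sum(A * outer(tm[, k2], tp[, l2]))
      out
    }
  }
  bwd_step <- if (engine == "fast") {
    function(X, tm, tp) tm %*% (X %*% t(tp))
  } else {
    function(X, tm, tp) {
      out <- matrix(0, K, Kp)
      for (k in seq_len(K)) for (l in seq_len(Kp))
        out[k, l] <- sum(X * outer(tm[k, ], tp[l, ]))
      out
    }
  }
  alpha <- array(0, c(K, Kp, n))
  alphapre <- array(0, c(K, Kp, n))
  scale <- numeric(n)
  Apre <- outer(maternal$init, paternal$init)
  for (i in seq_len(n)) {
    if (i > 1L)
      Apre <- fwd_step(matrix(alpha[, , i - 1L], K, Kp),
                       matrix(TM[, , i - 1L], K, K),
                       matrix(TP[, , i - 1L], Kp, Kp))
    A <- Apre * phis[[i]]
    scale[i] <- sum(A)
    if (scale[i] <= 0)
      stop("zero total probability at locus ", i, ": the reads are ",
           "impossible under the model; retrain with a positive ",
           "emission pseudocount")
    alphapre[, , i] <- Apre
    alpha[, , i] <- A / scale[i]
  }
  beta <- array(0, c(K, Kp, n))
  beta[, , n] <- 1
  if (n > 1L) for (i in (n - 1L):1L) {
    X <- (phis[[i + 1L]] * beta[, , i + 1L]) / scale[i + 1L]
    beta[, , i] <- bwd_step(X, matrix(TM[, , i], K, K),
                            matrix(TP[, , i], Kp, Kp))
  }
  loglik <- sum(log(scale)) + sum(lr$logc)
  loglik_backward <- log(sum(outer(maternal$init, paternal$init) *
                               phis[[1]] * beta[, , 1])) +
    sum(log(scale[-1])) + sum(lr$logc)
  list(alpha = alpha, alphapre = alphapre, beta = beta, scale = scale,
       loglik = loglik, loglik_backward = loglik_backward)
}

#' Posterior genotype marginals P(g_i | all reads)
#'
#' Combines the forward-backward tables with the per-genotype emission
#' split: P(g_i, r) is proportional to
#' sum_(f,f') alphapre_i(f,f') L_i(g) gamma_i(f,f',g) beta_i(f,f'), with
#' the locus-i emission counted exactly once; rows are normalized to
#' P(g_i | r). Given the tables this costs O(n K^2).
#'
#' @inheritParams forward_backward
#' @param tables optional precomputed result of [forward_backward()].
#' @return an `n x 3` matrix of posterior probabilities (rows sum to 1)
#'   with attribute `loglik` = log P(r). Rows with zero mass (possible
#'   only with zero-pseudocount emissions) are `NA` with a warning.
#' @export
genotype_posteriors <- function(maternal, paternal, lik,
                                engine = c("fast", "naive"),
                                tables = NULL) {
  engine <- match.arg(engine)
  .check_models(maternal, paternal)
  n <- maternal$n; K <- maternal$K; Kp <- paternal$K
  if (is.null(tables)) tables <- forward_backward(maternal, paternal, lik,
                                                  engine)
  lr <- .lik_rows(lik, n)
  post <- matrix(0, n, 3, dimnames = list(NULL, c("g0", "g1", "g2")))
  for (i in seq_len(n)) {
    g <- .gamma_tables(matrix(maternal$emis[, , i], K, 2L),
                       matrix(paternal$emis[, , i], Kp, 2L))
    ab <- tables$alphapre[, , i] * tables$beta[, , i]
    post[i, ] <- c(lr$L[i, 1] * sum(ab * g[[1]]),
                   lr$L[i, 2] * sum(ab * g[[2]]),
                   lr$L[i, 3] * sum(ab * g[[3]]))
  }
  tot <- rowSums(post)
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " loci with zero posterior mass")
    tot[bad] <- 1
    post[bad, ] <- NA_real_
  }
  post <- post / tot
  attr(post, "loglik") <- tables$loglik
  post
}

#' Model-implied genotype prior (no reads)
#'
#' The data-free per-locus genotype distribution implied by the two
#' founder HMMs; equals the posterior when no locus is covered. Used for
#' deterministic tie-breaking and for matching the single-SNP caller to
#' a K = 1 factorial model.
#'
#' @inheritParams forward_backward
#' @return an `n x 3` matrix.
#' @export
model_genotype_prior <- function(maternal, paternal = maternal) {
  .check_models(maternal, paternal)
  neutral <- matrix(1, maternal$n, 3)
  p <- genotype_posteriors(maternal, paternal, neutral)
  attr(p, "loglik") <- NULL
  p
}

#' Posterior decoding of genotype marginals
#'
#' Independently per locus, returns argmax_g P(g_i | r). Ties are broken
#' toward the genotype with the larger data-free model prior, then
#' toward the smaller genotype.
#'
#' @param post `n x 3` posterior matrix.
#' @param prior optional `n x 3` prior matrix used only for tie-breaks.
#' @return integer vector of genotypes in \{0, 1, 2\} (`NA` for `NA`
#'   posterior rows).
#' @export
posterior_decode <- function(post, prior = NULL) {
  g <- rep(NA_integer_, nrow(post))
  ok <- stats::complete.cases(post)
  if (any(ok))
    g[ok] <- .argmax_genotype(post[ok, , drop = FALSE],
                              if (!is.null(prior))
                                prior[ok, , drop = FALSE])
  g
}

#' No-call thresholding
#'
#' A locus is left uncalled when its maximum posterior falls below `t`,
#' trading call rate for concordance.
#'
#' @param calls a `geno_calls` data.frame.
#' @param threshold t in [0, 1).
#' @return the calls with sub-threshold genotypes set to `NA`.
#' @export
apply_no_call_threshold <- function(calls, threshold) {
  stopifnot(threshold >= 0, threshold < 1)
  maxp <- pmax(calls$p0, calls$p1, calls$p2)
  calls$genotype[is.na(maxp) | maxp < threshold] <- NA_integer_
  calls
}

#' LD-aware genotype calling (HF-HMM posterior decoding)
#'
#' The package's main caller: computes P(g_i | all reads) under the
#' factorial founder-HMM model and calls the maximum-posterior genotype
#' at every locus, in O(m + n K^3) time. Uncovered loci are retained and
#' imputed through linkage disequilibrium — that is the point of the
#' method.
#'
#' @param reads a [pileup_data] object (or a [genotype_likelihoods]
#'   matrix).
#' @param maternal fitted [hap_hmm] for the maternal population panel.
#' @param paternal fitted [hap_hmm] for the paternal population panel;
#'   defaults to the maternal model (a single panel serves both parents).
#' @param threshold no-call threshold on the maximum posterior.
#' @param engine forward-backward engine, see [forward_backward()].
#' @return a `geno_calls` data.frame with attributes `loglik` (total
#'   log-likelihood of the read data) and `posterior` (the full matrix).
#' @examples
#' pan <- sim_panel(n_snps = 60, n_haplotypes = 40, n_founders = 4, seed = 1)
#' fit <- hap_hmm(pan, K = 4, seed = 1)
#' ind <- sim_individual(fit, seed = 2)
#' rd <- sim_reads(ind$g, mean_coverage = 4, seed = 3)
#' calls <- call_ld(rd, fit)
#' mean(calls$genotype == ind$g)
#' @export
call_ld <- function(reads, maternal, paternal = maternal, threshold = 0,
                    engine = c("fast", "naive")) {
  lik <- if (inherits(reads, "read_pileup")) genotype_likelihoods(reads)
         else reads
  post <- genotype_posteriors(maternal, paternal, lik, engine)
  prior <- model_genotype_prior(maternal, paternal)
  g <- posterior_decode(post, prior)
  calls <- .new_geno_calls(seq_len(nrow(post)), g, post, "hmm")
  calls <- apply_no_call_threshold(calls, threshold)
  attr(calls, "loglik") <- attr(post, "loglik")
  attr(calls, "posterior") <- post
  calls
}

## Exact P(h | M) for every one of the 2^n haplotypes, by unscaled
## forward products. Oracle helper; n must be small.
.all_hap_probs <- function(hmm) {
  n <- hmm$n; K <- hmm$K
  H <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n), drop = FALSE]
  colnames(H) <- NULL
  p <- numeric(nrow(H))
  for (j in seq_len(nrow(H))) {
    e <- matrix(hmm$emis[, , 1], K, 2L)
    v <- hmm$init * e[, H[j, 1] + 1L]
    if (n > 1L) for (i in 2:n) {
      e <- matrix(hmm$emis[, , i], K, 2L)
      v <- (t(matrix(hmm$trans[, , i - 1L], K, K)) %*% v) * e[, H[j, i] + 1L]
    }
    p[j] <- sum(v)
  }
  list(haps = H, probs = p)
}

#' Brute-force genotype posteriors by haplotype-pair enumeration
#'
#' Exact P(g_i | r) computed directly from the model definition: sum
#' over all 4^n ordered haplotype pairs (h, h') of
#' P(h | M) P(h' | M') prod_i P(r_i | h_i + h'_i), binned by h_i + h'_i.
#' This is the normative oracle against which the forward-backward
#' implementation is verified; it is exponential in n.
#'
#' @inheritParams forward_backward
#' @param reads a [pileup_data] or likelihood matrix.
#' @return an `n x 3` posterior matrix with attribute `loglik`.
#' @export
brute_force_posteriors <- function(maternal, paternal, reads) {
  .check_models(maternal, paternal)
  n <- maternal$n
  if (n > 8) stop("brute-force enumeration is limited to n <= 8 loci")
  lik <- if (inherits(reads, "read_pileup")) genotype_likelihoods(reads)
         else reads
  L <- exp(.as_loglik_matrix(lik))
  hm <- .all_hap_probs(maternal)
  hp <- if (identical(paternal, maternal)) hm else .all_hap_probs(paternal)
  post <- matrix(0, n, 3)
  tot <- 0
  for (a in seq_len(nrow(hm$haps))) for (b in seq_len(nrow(hp$haps))) {
    g <- hm$haps[a, ] + hp$haps[b, ]
    w <- hm$probs[a] * hp$probs[b] * prod(L[cbind(seq_len(n), g + 1L)])
    tot <- tot + w
    post[cbind(seq_len(n), g + 1L)] <- post[cbind(seq_len(n), g + 1L)] + w
  }
  if (tot == 0) stop("zero total probability in enumeration")
  post <- post / tot
  attr(post, "loglik") <- log(tot)
  dimnames(post) <- list(NULL, c("g0", "g1", "g2"))
  post
}
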