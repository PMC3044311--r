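#' Assemble a founder-haplotype HMM from explicit parameters
#'
#' A K-founder left-to-right HMM over n SNP loci: hidden states are the
#' founder haplotypes F_i, emissions are the 0/1 alleles H_i, and each
#' observed haplotype is modelled as a recombination mosaic of founders.
#' Parameters are the initial distribution P(f_1), per-interval transition
#' matrices P(f_{i+1} | f_i), and per-locus emission matrices P(h_i | f_i).
#'
#' @param init length-K probability vector.
#' @param trans `K x K x (n-1)` array of row-stochastic transition
#'   matrices (`trans[, , i]` moves from locus i to i+1).
#' @param emis `K x 2 x n` array; `emis[, 1, i]` is P(h_i = 0 | f),
#'   `emis[, 2, i]` is P(h_i = 1 | f).
#' @return an object of class `hap_hmm`.
#' @export
hap_hmm_model <- function(init, trans, emis) {
  K <- length(init)
  emis <- array(emis, dim = c(K, 2L, length(emis) / (2L * K)))
  n <- dim(emis)[3]
  trans <- array(trans, dim = c(K, K, max(n - 1L, 0L)))
  m <- structure(list(K = K, n = n, init = init, trans = trans, emis = emis),
                 class = "hap_hmm")
  validate_hap_hmm(m)
  m
}

validate_hap_hmm <- function(m, tol = 1e-9) {
  with(m, {
    if (any(init < 0) || abs(sum(init) - 1) > tol)
      stop("initial founder distribution must be a probability vector")
    if (n > 1L) {
      rs <- apply(trans, 3, rowSums)
      if (any(trans < 0) || any(abs(rs - 1) > tol))
        stop("every transition row must be nonnegative and sum to 1")
    }
    es <- apply(emis, 3, rowSums)
    if (any(emis < 0) || any(abs(es - 1) > tol))
      stop("every emission row must be nonnegative and sum to 1")
  })
  invisible(m)
}

## Dirichlet(1)-perturbed uniform row: average of the uniform vector and a
## normalized vector of iid exponentials; breaks EM symmetry reproducibly.
.perturbed_rows <- function(nrow, ncol) {
  d <- matrix(stats::rexp(nrow * ncol), nrow)
  d <- d / rowSums(d)
  (matrix(1 / ncol, nrow, ncol) + d) / 2
}

.init_hap_hmm <- function(K, n) {
  init <- as.vector(.perturbed_rows(1L, K))
  trans <- array(0, c(K, K, max(n - 1L, 0L)))
  if (n > 1L) for (i in seq_len(n - 1L)) trans[, , i] <- .perturbed_rows(K, K)
  emis <- array(0, c(K, 2L, n))
  for (i in seq_len(n)) emis[, , i] <- .perturbed_rows(K, 2L)
  list(init = init, trans = trans, emis = emis)
}

#' Fit a founder-haplotype HMM to a phased panel by Baum-Welch
#'
#' Estimates P(f_1), P(f_{i+1} | f_i) and P(h_i | f_i) by
#' expectation-maximization over the panel haplotypes, treating each
#' haplotype as an independent emission sequence of the K-founder
#' left-to-right HMM. The E-step runs scaled forward-backward over all
#' haplotypes simultaneously; the M-step renormalizes expected counts
#' after adding `pseudocount` to every cell, so that no emission is ever
#' driven exactly to zero (a zero would make the corresponding read
#' allele impossible downstream).
#'
#' @param panel a [haplotype_panel].
#' @param K number of founder haplotypes (default 7).
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood gain drops below `tol`.
#' @param seed RNG seed for the perturbed-uniform initialization; fits
#'   with the same panel, configuration and seed are identical.
#' @param pseudocount added to expected counts before renormalization.
#' @param n_restarts independent seeded starts; the fit with the best
#'   final log-likelihood is returned.
#' @param verbose print the per-iteration log-likelihood.
#' @return an object of class `hap_hmm` with parameter arrays as in
#'   [hap_hmm_model()] plus `logLik` (final), `trace` (per-iteration
#'   log-likelihoods), `iterations`, `converged` and `seed`.
#' @examples
#' pan <- sim_panel(n_snps = 40, n_haplotypes = 30, n_founders = 3, seed = 1)
#' fit <- hap_hmm(pan, K = 3, seed = 1)
#' fit
#' @export
hap_hmm <- function(panel, K = 7, max_iter = 100, tol = 1e-6, seed = NULL,
                    pseudocount = 1e-6, n_restarts = 1, verbose = FALSE) {
  stopifnot(inherits(panel, "haplotype_panel"), K >= 1, tol > 0,
            max_iter >= 1, pseudocount >= 0, n_restarts >= 1)
  H <- panel$haplotypes
  if (nrow(H) == 0L || ncol(H) == 0L) stop("empty panel")
  if (K > nrow(unique(H)))
    warning("K = ", K, " exceeds the number of distinct panel haplotypes")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .baum_welch_once(H, K, max_iter, tol, seed + r - 1L,
                            pseudocount, verbose)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  best$loci <- panel$loci
  best$call <- match.call()
  class(best) <- "hap_hmm"
  validate_hap_hmm(best)
  best
}

.baum_welch_once <- function(H, K, max_iter, tol, seed, pseudocount,
                             verbose) {
  n <- ncol(H); N <- nrow(H)
  set.seed(seed)
  par <- .init_hap_hmm(K, n)
  init <- par$init; trans <- par$trans; emis <- par$emis
  a1 <- H + 1L                      # column index into emission matrices
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## --- E-step: scaled forward-backward, vectorized over haplotypes ---
    alpha <- array(0, c(N, K, n))   # scaled: rows sum to 1
    cs <- matrix(0, N, n)           # per-haplotype scale factors
    emis_at <- function(i) {
      ## N x K matrix of P(h_s,i | f = k)
      e <- matrix(emis[, , i], K, 2L)
      t(e[, a1[, i], drop = FALSE])
    }
    a <- matrix(init, N, K, byrow = TRUE) * emis_at(1L)
    cs[, 1] <- rowSums(a)
    a <- a / cs[, 1]
    alpha[, , 1] <- a
    if (n > 1L) for (i in 2:n) {
      a <- (a %*% trans[, , i - 1L]) * emis_at(i)
      cs[, i] <- rowSums(a)
      a <- a / cs[, i]
      alpha[, , i] <- a
    }
    ll <- sum(log(cs))
    trace <- c(trace, ll)
    if (verbose) message(sprintf("iter %3d  logLik %.6f", iter, ll))

    beta <- matrix(1, N, K)
    new_init <- numeric(K)
    new_trans <- array(pseudocount, c(K, K, max(n - 1L, 0L)))
    new_emis <- array(pseudocount, c(K, 2L, n))
    g <- alpha[, , n] * beta        # posterior founder weights at locus n
    for (a0 in 1:2)
      new_emis[, a0, n] <- new_emis[, a0, n] + colSums(g[a1[, n] == a0, ,
                                                         drop = FALSE])
    if (n > 1L) for (i in (n - 1L):1L) {
      Bnext <- emis_at(i + 1L) * beta / cs[, i + 1L]
      new_trans[, , i] <- new_trans[, , i] +
        trans[, , i] * (t(alpha[, , i]) %*% Bnext)
      beta <- Bnext %*% t(trans[, , i])
      g <- alpha[, , i] * beta
      for (a0 in 1:2)
        new_emis[, a0, i] <- new_emis[, a0, i] + colSums(g[a1[, i] == a0, ,
                                                           drop = FALSE])
    }
    new_init <- colSums(g) + pseudocount

    ## --- M-step ---
    init <- new_init / sum(new_init)
    if (n > 1L) for (i in seq_len(n - 1L))
      trans[, , i] <- new_trans[, , i] / rowSums(new_trans[, , i,
                                                           drop = FALSE])
    for (i in seq_len(n)) {
      e <- matrix(new_emis[, , i], K, 2L)
      emis[, , i] <- e / rowSums(e)
    }
    if (iter > 1L && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(K = K, n = n, init = init, trans = trans, emis = emis,
       logLik = trace[length(trace)], trace = trace,
       iterations = length(trace), converged = converged, seed = seed,
       pseudocount = pseudocount)
}

#' Log-likelihood of haplotypes under a founder HMM
#'
#' Scaled forward algorithm; numerically stable for n up to 1e5 loci.
#'
#' @param hmm a `hap_hmm`.
#' @param h a 0/1 vector of length n, or a matrix with one haplotype per
#'   row.
#' @return a numeric vector of log-probabilities, one per haplotype.
#' @export
haplotype_loglik <- function(hmm, h) {
  stopifnot(inherits(hmm, "hap_hmm"))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (ncol(h) != hmm$n)
    stop("haplotype length ", ncol(h), " does not match model n = ", hmm$n)
  if (!all(h %in% c(0, 1))) stop("haplotype entries must be 0 or 1")
  N <- nrow(h); K <- hmm$K
  a1 <- h + 1L
  ll <- numeric(N)
  e <- matrix(hmm$emis[, , 1], K, 2L)
  a <- matrix(hmm$init, N, K, byrow = TRUE) * t(e[, a1[, 1], drop = FALSE])
  s <- rowSums(a); ll <- log(s); a <- a / s
  if (hmm$n > 1L) for (i in 2:hmm$n) {
    e <- matrix(hmm$emis[, , i], K, 2L)
    a <- (a %*% hmm$trans[, , i - 1L]) * t(e[, a1[, i], drop = FALSE])
    s <- rowSums(a); ll <- ll + log(s); a <- a / s
  }
  ll
}

#' @export
print.hap_hmm <- function(x, ...) {
  cat(sprintf("Founder-haplotype HMM: K = %d founders, n = %d SNPs\n",
              x$K, x$n))
  if (!is.null(x$logLik))
    cat(sprintf("  panel logLik %.3f after %d EM iterations (%s)\n",
                x$logLik, x$iterations,
                if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.hap_hmm <- function(object, ...) {
  p1 <- colSums(object$init * matrix(object$emis[, 2, ], object$K))
  stay <- if (object$n > 1L) mean(apply(object$trans, 3,
                                        function(m) mean(diag(m)))) else NA
  out <- list(K = object$K, n = object$n, logLik = object$logLik,
              iterations = object$iterations, converged = object$converged,
              mean_self_transition = stay,
              allele1_freq_first_locus = p1[1])
  class(out) <- "summary.hap_hmm"
  out
}

#' @export
print.summary.hap_hmm <- function(x, ...) {
  cat(sprintf("Founder-haplotype HMM (K = %d, n = %d)\n", x$K, x$n))
  cat(sprintf("  logLik: %.3f  iterations: %d  converged: %s\n",
              x$logLik, x$iterations, x$converged))
  if (!is.na(x$mean_self_transition))
    cat(sprintf("  mean self-transition (founder persistence): %.4f\n",
                x$mean_self_transition))
  invisible(x)
}

#' @export
logLik.hap_hmm <- function(object, ...) {
  ll <- object$logLik
  attr(ll, "df") <- with(object, (K - 1) + (n - 1) * K * (K - 1) + n * K)
  class(ll) <- "logLik"
  ll
}

#' @export
coef.hap_hmm <- function(object, ...) {
  object[c("init", "trans", "emis")]
}

#' Sample haplotypes from a fitted founder HMM
#'
#' Draws founder paths from the Markov chain and alleles from the
#' per-locus emissions.
#'
#' @param object a `hap_hmm`.
#' @param nsim number of haplotypes to draw.
#' @param seed optional seed, applied with `set.seed`.
#' @param ... unused.
#' @return an `nsim x n` 0/1 matrix with the founder paths attached as
#'   attribute `"founders"`.
#' @export
simulate.hap_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$K; n <- object$n
  h <- matrix(0L, nsim, n)
  f <- matrix(0L, nsim, n)
  f[, 1] <- sample.int(K, nsim, replace = TRUE, prob = object$init)
  if (n > 1L) for (i in 2:n) {
    tm <- matrix(object$trans[, , i - 1L], K, K)
    f[, i] <- vapply(f[, i - 1L], function(k)
      sample.int(K, 1L, prob = tm[k, ]), integer(1))
  }
  for (i in seq_len(n)) {
    p1 <- matrix(object$emis[, , i], K, 2L)[f[, i], 2]
    h[, i] <- as.integer(stats::runif(nsim) < p1)
  }
  attr(h, "founders") <- f
  h
}

#' Write / read a founder HMM as versioned JSON
#'
#' Parameters are stored at 17 significant digits so the round trip
#' reproduces every double exactly.
#'
#' @param hmm a `hap_hmm`.
#' @param path file path.
#' @return `read_hap_hmm` returns the restored `hap_hmm`.
#' @export
write_hap_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "hap_hmm"))
  obj <- list(format = "ldgeno_hap_hmm", version = 1L,
              K = hmm$K, n = hmm$n,
              init = hmm$init,
              trans = as.vector(hmm$trans),
              emis = as.vector(hmm$emis),
              logLik = hmm$logLik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_hap_hmm
#' @export
read_hap_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "ldgeno_hap_hmm")
    stop("not an ldgeno HMM model file")
  K <- obj$K; n <- obj$n
  if (length(obj$trans) != K * K * max(n - 1, 0) ||
      length(obj$emis) != K * 2 * n || length(obj$init) != K)
    stop("model file is truncated or has inconsistent dimensions")
  m <- hap_hmm_model(obj$init,
                     array(obj$trans, c(K, K, max(n - 1L, 0L))),
                     array(obj$emis, c(K, 2L, n)))
  m$logLik <- obj$logLik
  m
}
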