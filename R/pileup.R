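#' Convert a Phred quality to an error probability
#'
#' eps = 10^(-q/10), capped at 0.5: an allele call wrong more than half
#' the time carries no usable information, and the cap keeps q = 0 reads
#' from degenerating.
#'
#' @param q nonnegative integer Phred score(s).
#' @return error probabilities in (0, 0.5].
#' @examples
#' phred_to_error(c(0, 10, 20, 30))
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("Phred scores must be nonnegative")
  pmin(10^(-q / 10), 0.5)
}

#' Per-locus read observations (pileup)
#'
#' Container for all allele observations over `n` SNP loci. Each
#' observation is one read's base call at one locus, with its error
#' probability (from the Phred score) and a mapping confidence used as
#' an exponent weight on that read's likelihood factor. Reads spanning
#' several SNPs are represented as independent per-SNP observations.
#'
#' @param locus 1-based locus index per observation.
#' @param allele observed allele code, 0 or 1.
#' @param phred Phred quality per observation (ignored if `error_prob`
#'   is given).
#' @param error_prob per-observation error probability in (0, 0.5];
#'   defaults to `phred_to_error(phred)`.
#' @param map_conf mapping confidence m(r) in (0, 1]; default 1.
#' @param n number of loci; defaults to `max(locus)`.
#' @return an object of class `read_pileup`: a data.frame of
#'   observations with attributes `n` (locus count) and `m` (total
#'   observation count).
#' @export
pileup_data <- function(locus, allele, phred = NULL, error_prob = NULL,
                        map_conf = 1, n = NULL) {
  m <- length(locus)
  if (is.null(error_prob)) {
    if (is.null(phred)) stop("supply phred or error_prob")
    error_prob <- phred_to_error(phred)
  }
  if (is.null(phred)) phred <- round(-10 * log10(pmax(error_prob, 1e-12)))
  df <- data.frame(locus = as.integer(locus), allele = as.integer(allele),
                   phred = as.numeric(phred),
                   error_prob = as.numeric(error_prob),
                   map_conf = as.numeric(rep_len(map_conf, m)))
  if (m > 0 && !all(df$allele %in% c(0L, 1L)))
    stop("allele codes must be 0 or 1 (non-panel alleles are dropped ",
         "at load time)")
  if (m > 0 && (any(df$error_prob <= 0) || any(df$error_prob > 0.5)))
    stop("error probabilities must lie in (0, 0.5]")
  if (m > 0 && (any(df$map_conf <= 0) || any(df$map_conf > 1)))
    stop("mapping confidences must lie in (0, 1]")
  if (is.null(n)) n <- if (m > 0) max(df$locus) else 0L
  if (m > 0 && (any(df$locus < 1L) || any(df$locus > n)))
    stop("locus indices must lie in 1..n")
  structure(df, n = as.integer(n), m = m,
            class = c("read_pileup", "data.frame"))
}

#' @export
print.read_pileup <- function(x, ...) {
  n <- attr(x, "n")
  cov <- tabulate(x$locus, nbins = n)
  cat(sprintf("Read pileup: %d observations over %d loci (mean coverage %.2f, %d uncovered)\n",
              attr(x, "m"), n, mean(cov), sum(cov == 0)))
  invisible(x)
}

#' Genotype likelihood triple for one site
#'
#' For observations r_1..r_c at one locus with alleles a_j, error
#' probabilities eps_j and mapping confidences m_j, the per-read factors
#' are (1 - eps) for the homozygote matching the read allele, eps for the
#' mismatching homozygote, and exactly 1/2 for the heterozygote (either
#' chromosome is sampled with probability 1/2; the correct-call and
#' error paths sum to (1-eps)/2 + eps/2). Each factor is raised to the
#' power m_j, so a read mapped with confidence m counts as an m-fraction
#' of a confidently mapped read.
#'
#' @param allele 0/1 vector of observed alleles at the site.
#' @param error_prob matching vector of error probabilities.
#' @param map_conf matching vector of mapping confidences (default 1).
#' @return likelihood triple `c(L0, L1, L2)` = P(reads | g) for
#'   g = 0, 1, 2. An empty site gives `c(1, 1, 1)`.
#' @examples
#' site_likelihoods(0, 0.01)            # one high-quality ref read
#' site_likelihoods(c(0, 1), c(0.01, 0.01))
#' @export
site_likelihoods <- function(allele, error_prob, map_conf = 1) {
  if (length(allele) == 0L) return(c(1, 1, 1))
  map_conf <- rep_len(map_conf, length(allele))
  w0 <- ifelse(allele == 0L, 1 - error_prob, error_prob)
  w2 <- ifelse(allele == 1L, 1 - error_prob, error_prob)
  c(exp(sum(map_conf * log(w0))),
    exp(sum(map_conf * log(0.5))),
    exp(sum(map_conf * log(w2))))
}

#' Genotype likelihoods for every locus of a pileup
#'
#' Computes the per-locus triples P(r_i | g) for g in \{0, 1, 2\} in one
#' pass over the observations (O(m) time), accumulating in log space.
#'
#' @param reads a [pileup_data] object.
#' @return an object of class `geno_lik`: an `n x 3` matrix of linear
#'   likelihoods with attribute `logLik` holding the same triples in log
#'   space (used internally to avoid underflow at extreme depth).
#'   Uncovered loci have the neutral triple (1, 1, 1).
#' @export
genotype_likelihoods <- function(reads) {
  stopifnot(inherits(reads, "read_pileup"))
  n <- attr(reads, "n")
  ll <- matrix(0, n, 3, dimnames = list(NULL, c("g0", "g1", "g2")))
  if (nrow(reads) > 0) {
    w0 <- ifelse(reads$allele == 0L, 1 - reads$error_prob, reads$error_prob)
    w2 <- ifelse(reads$allele == 1L, 1 - reads$error_prob, reads$error_prob)
    mc <- reads$map_conf
    ll[, 1] <- .accum(reads$locus, mc * log(w0), n)
    ll[, 2] <- .accum(reads$locus, mc * log(0.5), n)
    ll[, 3] <- .accum(reads$locus, mc * log(w2), n)
  }
  structure(exp(ll), logLik = ll, class = c("geno_lik", "matrix"))
}

.accum <- function(idx, x, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

.as_loglik_matrix <- function(lik) {
  if (inherits(lik, "geno_lik")) attr(lik, "logLik")
  else log(as.matrix(lik))
}

.new_geno_calls <- function(locus, genotype, post, method) {
  df <- data.frame(locus = as.integer(locus),
                   genotype = as.integer(genotype),
                   p0 = post[, 1], p1 = post[, 2], p2 = post[, 3],
                   method = method, stringsAsFactors = FALSE)
  class(df) <- c("geno_calls", "data.frame")
  df
}

#' @export
print.geno_calls <- function(x, ...) {
  nc <- sum(is.na(x$genotype))
  cat(sprintf("Genotype calls (%s): %d loci, %d no-calls (call rate %.3f)\n",
              paste(unique(x$method), collapse = ","), nrow(x), nc,
              1 - nc / nrow(x)))
  tab <- table(factor(x$genotype, levels = 0:2))
  cat(sprintf("  called 0/1/2: %d / %d / %d\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
summary.geno_calls <- function(object, ...) {
  maxp <- pmax(object$p0, object$p1, object$p2)
  out <- list(n = nrow(object), no_calls = sum(is.na(object$genotype)),
              genotype_counts = table(factor(object$genotype, levels = 0:2)),
              mean_max_posterior = mean(maxp),
              method = unique(object$method))
  class(out) <- "summary.geno_calls"
  out
}

#' @export
print.summary.geno_calls <- function(x, ...) {
  cat(sprintf("Genotype calls by %s over %d loci\n",
              paste(x$method, collapse = ","), x$n))
  cat(sprintf("  no-calls: %d   mean max posterior: %.4f\n",
              x$no_calls, x$mean_max_posterior))
  print(x$genotype_counts)
  invisible(x)
}

## argmax with deterministic tie-breaking: larger prior first, then the
## smaller genotype (homozygous reference)
.argmax_genotype <- function(post, prior = NULL) {
  if (is.null(prior)) prior <- matrix(0, nrow(post), 3)
  apply(cbind(post, prior), 1, function(r) {
    p <- r[1:3]; pri <- r[4:6]
    cand <- which(p == max(p))
    if (length(cand) > 1L) cand <- cand[pri[cand] == max(pri[cand])]
    cand[1] - 1L
  })
}

#' Single-SNP Bayesian genotype caller
#'
#' LD-oblivious baseline: at each locus independently, posterior(g) is
#' proportional to P(r_i | g) P(G_i = g) with the panel-derived prior,
#' and the maximum-posterior genotype is called. A locus without reads
#' returns the prior itself.
#'
#' @param reads a [pileup_data] object, or a precomputed
#'   [genotype_likelihoods] matrix.
#' @param prior `n x 3` prior matrix (e.g. from [genotype_prior()]), or
#'   a single triple recycled across loci.
#' @return a `geno_calls` data.frame (`locus`, `genotype`, posterior
#'   triple `p0/p1/p2`, `method`); genotype is `NA` where likelihood and
#'   prior support are disjoint (all three numerators zero).
#' @export
call_single_snp <- function(reads, prior) {
  ll <- if (inherits(reads, "read_pileup"))
    .as_loglik_matrix(genotype_likelihoods(reads))
  else .as_loglik_matrix(reads)
  n <- nrow(ll)
  if (is.null(dim(prior))) prior <- matrix(prior, n, 3, byrow = TRUE)
  if (any(abs(rowSums(prior) - 1) > 1e-6))
    stop("prior rows must sum to 1")
  num <- exp(ll - apply(ll, 1, max)) * prior
  tot <- rowSums(num)
  bad <- tot == 0
  if (any(bad))
    warning(sum(bad), " loci with zero posterior mass left uncalled")
  post <- num / ifelse(tot == 0, 1, tot)
  g <- .argmax_genotype(post, prior)
  g[bad] <- NA_integer_
  .new_geno_calls(seq_len(n), g, post, "single_snp")
}

#' Binomial-test genotype caller
#'
#' LD-oblivious baseline reconstructed from the classical shotgun
#' genotyping recipe: a site is called heterozygous when both alleles
#' are covered at least `min_allele_cov` times and a two-sided exact
#' binomial test of the allele counts against 0.5 does not reject at
#' level `alpha`; otherwise the majority-allele homozygote is called.
#' Uncovered loci are no-calls. Posteriors are degenerate 0/1
#' indicators of the call.
#'
#' @param reads a [pileup_data] object.
#' @param alpha rejection threshold of the binomial test (default 0.01).
#' @param min_allele_cov minimum coverage of each allele required for a
#'   heterozygous call (default 1).
#' @return a `geno_calls` data.frame.
#' @export
call_binomial <- function(reads, alpha = 0.01, min_allele_cov = 1) {
  stopifnot(inherits(reads, "read_pileup"))
  n <- attr(reads, "n")
  c1 <- .accum(reads$locus, as.numeric(reads$allele), n)
  cov <- .accum(reads$locus, rep(1, nrow(reads)), n)
  c0 <- cov - c1
  g <- rep(NA_integer_, n)
  for (i in which(cov > 0)) {
    if (min(c0[i], c1[i]) >= min_allele_cov &&
        stats::binom.test(c1[i], cov[i], 0.5)$p.value >= alpha) {
      g[i] <- 1L
    } else {
      g[i] <- if (c1[i] > c0[i]) 2L else if (c0[i] > c1[i]) 0L else 1L
    }
  }
  post <- matrix(0, n, 3)
  post[cbind(which(!is.na(g)), g[!is.na(g)] + 1L)] <- 1
  post[is.na(g), ] <- NA_real_
  .new_geno_calls(seq_len(n), g, post, "binomial")
}

#' Read a pileup TSV
#'
#' Expected columns: `chrom`, `pos`, `allele`, `phred`, and optionally
#' `map_conf` and `read_id`. `allele` is either the 0/1 panel code or a
#' base symbol matched against the locus alleles. Rows whose allele is
#' not one of the two panel alleles are dropped (with a message), as are
#' rows at positions absent from `loci`.
#'
#' @param path TSV file path.
#' @param loci locus table from a [haplotype_panel] (`$loci`).
#' @return a [pileup_data] object over `nrow(loci)` loci.
#' @export
read_pileup <- function(path, loci) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  req <- c("chrom", "pos", "allele", "phred")
  if (!all(req %in% names(tab)))
    stop("pileup file must have columns ", paste(req, collapse = ", "))
  key <- paste(loci$chrom, loci$pos)
  idx <- match(paste(tab$chrom, tab$pos), key)
  unknown <- is.na(idx)
  if (any(unknown))
    message(sum(unknown), " observations at positions not in the panel ",
            "were dropped")
  tab <- tab[!unknown, , drop = FALSE]; idx <- idx[!unknown]
  al <- as.character(tab$allele)
  code <- ifelse(al %in% c("0", "1"), suppressWarnings(as.integer(al)),
                 ifelse(al == loci$allele0[idx], 0L,
                        ifelse(al == loci$allele1[idx], 1L, NA_integer_)))
  offpanel <- is.na(code)
  if (any(offpanel))
    message(sum(offpanel), " observations with non-panel alleles were ",
            "dropped")
  keep <- !offpanel
  mc <- if ("map_conf" %in% names(tab)) tab$map_conf else 1
  pileup_data(locus = idx[keep], allele = code[keep],
              phred = tab$phred[keep],
              map_conf = if (length(mc) > 1) mc[keep] else mc,
              n = nrow(loci))
}

#' Write a pileup TSV
#'
#' @param reads a [pileup_data] object.
#' @param path output path.
#' @param loci locus table supplying `chrom`/`pos` per locus index.
#' @export
write_pileup <- function(reads, path, loci) {
  out <- data.frame(chrom = loci$chrom[reads$locus],
                    pos = loci$pos[reads$locus],
                    allele = reads$allele, phred = reads$phred,
                    map_conf = reads$map_conf)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotype calls as TSV
#'
#' Columns: `chrom`, `pos`, `call` (0/1/2 or `.` for no-call), posterior
#' triple `p0 p1 p2`, `method`.
#'
#' @param calls a `geno_calls` data.frame.
#' @param path output path.
#' @param loci optional locus table; defaults to chrom "1", pos = index.
#' @export
write_calls <- function(calls, path, loci = NULL) {
  if (is.null(loci))
    loci <- data.frame(chrom = "1", pos = calls$locus)
  out <- data.frame(chrom = loci$chrom[calls$locus],
                    pos = loci$pos[calls$locus],
                    call = ifelse(is.na(calls$genotype), ".",
                                  as.character(calls$genotype)),
                    p0 = sprintf("%.6f", calls$p0),
                    p1 = sprintf("%.6f", calls$p1),
                    p2 = sprintf("%.6f", calls$p2),
                    method = calls$method)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotype calls written by [write_calls()]
#'
#' @param path TSV path.
#' @param loci optional locus table used to map positions back to
#'   indices; defaults to pos = index.
#' @return a `geno_calls` data.frame.
#' @export
read_calls <- function(path, loci = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  locus <- if (is.null(loci)) tab$pos
           else match(paste(tab$chrom, tab$pos), paste(loci$chrom, loci$pos))
  g <- suppressWarnings(as.integer(tab$call))
  .new_geno_calls(locus, g, cbind(tab$p0, tab$p1, tab$p2), tab$method)
}
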