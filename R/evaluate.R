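#' Genotype concordance against a gold standard
#'
#' Compares called genotypes with truth, reporting overall, homozygous
#' (truth 0 or 2) and heterozygous (truth 1) concordance, the call rate,
#' and the 3 x 4 confusion table (truth by call, with a no-call column).
#' By default no-calls are excluded from concordance numerators and
#' denominators (the microarray no-call convention) but counted against
#' the call rate; `nocall_as_error = TRUE` counts them as errors
#' instead.
#'
#' @param calls a `geno_calls` data.frame.
#' @param truth integer vector of true genotypes in \{0, 1, 2\}, aligned
#'   with `calls$locus`.
#' @param nocall_as_error count no-calls as discordant.
#' @return an object of class `concordance_report`.
#' @export
concordance <- function(calls, truth, nocall_as_error = FALSE) {
  stopifnot(inherits(calls, "geno_calls"))
  truth <- as.integer(truth)
  if (length(truth) < max(calls$locus)) stop("truth shorter than calls")
  tr <- truth[calls$locus]
  g <- calls$genotype
  called <- !is.na(g)
  if (!any(called)) stop("zero evaluable loci: every locus is a no-call")
  conf <- table(factor(tr, levels = 0:2),
                factor(ifelse(called, g, 3L), levels = 0:3),
                dnn = c("truth", "call"))
  colnames(conf) <- c("0", "1", "2", "no_call")
  hit <- called & g == tr
  denom <- function(sel) if (nocall_as_error) sum(sel) else sum(sel & called)
  hom <- tr %in% c(0L, 2L); het <- tr == 1L
  rep <- list(
    n_eval = length(tr),
    overall = sum(hit) / denom(rep(TRUE, length(tr))),
    homozygous = if (any(hom)) sum(hit & hom) / denom(hom) else NA_real_,
    heterozygous = if (any(het)) sum(hit & het) / denom(het) else NA_real_,
    call_rate = mean(called),
    confusion = conf,
    nocall_as_error = nocall_as_error)
  class(rep) <- "concordance_report"
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d loci (call rate %.4f)\n",
              x$n_eval, x$call_rate))
  cat(sprintf("  overall %.4f   homozygous %.4f   heterozygous %.4f\n",
              x$overall, x$homozygous, x$heterozygous))
  if (x$nocall_as_error) cat("  (no-calls counted as errors)\n")
  invisible(x)
}

#' Concordance / call-rate tradeoff over a threshold grid
#'
#' Re-thresholds the posterior calls at each value of `thresholds` and
#' evaluates concordance; raising the threshold trades call rate for
#' accuracy on the retained calls.
#'
#' @param calls a `geno_calls` data.frame carrying posteriors.
#' @param truth true genotype vector.
#' @param thresholds ascending grid of no-call thresholds in [0, 1).
#' @return a data.frame with one row per threshold: `threshold`,
#'   `call_rate`, `overall`, `homozygous`, `heterozygous`.
#' @export
tradeoff_curve <- function(calls, truth, thresholds = c(0, 0.9, 0.99)) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  rows <- lapply(thresholds, function(t) {
    r <- concordance(apply_no_call_threshold(calls, t), truth)
    data.frame(threshold = t, call_rate = r$call_rate,
               overall = r$overall, homozygous = r$homozygous,
               heterozygous = r$heterozygous)
  })
  do.call(rbind, rows)
}

#' Reference-allele coverage ratios at heterozygous loci
#'
#' For every truth-heterozygous locus with coverage at least 1, the
#' fraction of its observations reporting allele 0 (the reference).
#' Unbiased sequencing gives a mean near 0.5; an excess indicates
#' reference-allele bias, which degrades heterozygous calling.
#'
#' @param reads a [pileup_data] object.
#' @param truth true genotype vector.
#' @return list with `ratios` (per covered het locus), `mean`, and
#'   `n_loci`.
#' @export
ref_allele_ratio <- function(reads, truth) {
  stopifnot(inherits(reads, "read_pileup"))
  n <- attr(reads, "n")
  cov <- .accum(reads$locus, rep(1, nrow(reads)), n)
  n0 <- .accum(reads$locus, as.numeric(reads$allele == 0L), n)
  het <- which(truth == 1L & cov > 0)
  if (length(het) == 0L) stop("no covered heterozygous loci")
  ratios <- n0[het] / cov[het]
  list(ratios = ratios, mean = mean(ratios), n_loci = length(het))
}

#' Compare calling methods across coverage subsets
#'
#' Downsamples the read set to each fraction (nested subsets under one
#' seed), calls genotypes with each method, and evaluates concordance
#' against the truth. This reproduces the coverage-titration
#' methodology: LD-aware calling degrades most gracefully as coverage
#' drops because uncovered loci are imputed from linked neighbours.
#'
#' @param reads a [pileup_data] object.
#' @param maternal,paternal fitted [hap_hmm] models (needed for the
#'   `"hmm"` method).
#' @param prior `n x 3` prior matrix for the `"single_snp"` method
#'   (e.g. [genotype_prior()]).
#' @param truth true genotype vector.
#' @param fractions coverage fractions to evaluate.
#' @param methods subset of `c("hmm", "single_snp", "binomial")`.
#' @param seed seed for the (nested) downsampling.
#' @return a data.frame with columns `method`, `fraction`, `call_rate`,
#'   `overall`, `homozygous`, `heterozygous`.
#' @export
compare_methods <- function(reads, maternal, paternal = maternal,
                            prior = NULL, truth,
                            fractions = c(1/16, 1/8, 1/4, 1/2, 1),
                            methods = c("hmm", "single_snp", "binomial"),
                            seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (f in sort(fractions)) {
    sub <- downsample_reads(reads, f, seed = seed, mode = "exact")
    for (meth in methods) {
      calls <- switch(meth,
        hmm = call_ld(sub, maternal, paternal),
        single_snp = {
          if (is.null(prior)) stop("single_snp needs a prior")
          call_single_snp(sub, prior)
        },
        binomial = call_binomial(sub))
      r <- concordance(calls, truth)
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, fraction = f, call_rate = r$call_rate,
                   overall = r$overall, homozygous = r$homozygous,
                   heterozygous = r$heterozygous)
    }
  }
  do.call(rbind, rows)
}
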