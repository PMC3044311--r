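#' Construct a phased haplotype reference panel
#'
#' A panel is a matrix of phased haplotypes over `n` ordered biallelic SNP
#' loci, with alleles coded 0/1 (0 conventionally the reference allele).
#' Rows are haplotypes, columns are loci.
#'
#' @param haplotypes numeric or integer matrix with entries in \{0, 1\};
#'   one row per haplotype, one column per SNP locus. At least 2 rows.
#' @param loci optional data.frame describing the loci, with columns
#'   `chrom`, `pos`, `allele0`, `allele1`. Positions must be strictly
#'   increasing within each chromosome. If `NULL`, placeholder loci on
#'   chromosome "1" at positions `1..n` with alleles A/G are created.
#' @return an object of class `haplotype_panel` with elements
#'   `haplotypes` (integer matrix) and `loci` (data.frame with an added
#'   1-based `index` column).
#' @examples
#' p <- haplotype_panel(rbind(c(0, 1, 0), c(1, 1, 0)))
#' p
#' @export
haplotype_panel <- function(haplotypes, loci = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) < 2L)
    stop("a haplotype panel needs at least 2 haplotypes")
  if (!all(haplotypes %in% c(0, 1)))
    stop("panel haplotype entries must all be 0 or 1")
  storage.mode(haplotypes) <- "integer"
  n <- ncol(haplotypes)
  if (is.null(loci)) {
    loci <- data.frame(chrom = "1", pos = seq_len(n),
                       allele0 = "A", allele1 = "G",
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci)
  req <- c("chrom", "pos", "allele0", "allele1")
  if (!all(req %in% names(loci)))
    stop("loci must have columns ", paste(req, collapse = ", "))
  if (nrow(loci) != n)
    stop("loci (", nrow(loci), " rows) do not match panel width (", n, ")")
  if (any(loci$allele0 == loci$allele1))
    stop("allele0 must differ from allele1 at every locus")
  for (chr in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == chr]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  loci$index <- seq_len(n)
  structure(list(haplotypes = haplotypes, loci = loci),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Haplotype panel:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "SNPs\n")
  f <- colMeans(x$haplotypes)
  cat(sprintf("  allele-1 frequency: min %.3f / median %.3f / max %.3f\n",
              min(f), stats::median(f), max(f)))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haplotypes)

#' Read a panel from hap/legend files
#'
#' The legend file is whitespace-delimited with a header line
#' `id chrom pos allele0 allele1`; the hap file holds one row per
#' haplotype of space-separated 0/1 codes, one column per legend SNP.
#'
#' @param hap_file path to the hap file.
#' @param legend_file path to the legend file.
#' @return a [haplotype_panel].
#' @export
read_hap_legend <- function(hap_file, legend_file) {
  leg <- utils::read.table(legend_file, header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "allele0", "allele1")
  if (!all(req %in% names(leg)))
    stop("legend file must have columns ", paste(req, collapse = ", "))
  rows <- readLines(hap_file)
  rows <- rows[nzchar(trimws(rows))]
  mat <- lapply(rows, function(r) strsplit(trimws(r), "[ \t]+")[[1]])
  len <- lengths(mat)
  if (length(unique(len)) > 1L)
    stop("ragged hap file: rows of differing length (",
         paste(unique(len), collapse = ", "), ")")
  if (len[1] != nrow(leg))
    stop("hap rows have ", len[1], " alleles but legend describes ",
         nrow(leg), " SNPs")
  bad <- !unlist(mat) %in% c("0", "1")
  if (any(bad))
    stop("non-{0,1} allele code in hap file: ",
         paste(unique(unlist(mat)[bad]), collapse = ", "))
  hap <- matrix(as.integer(unlist(mat)), nrow = length(mat), byrow = TRUE)
  haplotype_panel(hap, leg[c("chrom", "pos", "allele0", "allele1")])
}

#' Read a panel from a phased VCF
#'
#' Only biallelic SNP records with fully phased GT fields are accepted;
#' each diploid sample contributes two haplotype rows (left then right
#' of the `|` separator).
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a [haplotype_panel].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- nchar(ref) != 1L | nchar(alt) != 1L | grepl(",", alt)
  if (any(bad))
    stop("non-biallelic-SNP record at ", fix[which(bad)[1], "CHROM"], ":",
         fix[which(bad)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (any(is.na(gt)) || any(!grepl("^[01]\\|[01]$", gt)))
    stop("all GT fields must be phased biallelic calls of the form 0|1")
  n <- nrow(gt)
  haps <- matrix(0L, nrow = 2L * ncol(gt), ncol = n)
  for (s in seq_len(ncol(gt))) {
    parts <- do.call(rbind, strsplit(gt[, s], "|", fixed = TRUE))
    haps[2L * s - 1L, ] <- as.integer(parts[, 1])
    haps[2L * s, ]      <- as.integer(parts[, 2])
  }
  loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     allele0 = ref, allele1 = alt, stringsAsFactors = FALSE)
  haplotype_panel(haps, loci)
}

#' Per-locus genotype prior from a reference panel
#'
#' Estimates the population genotype frequencies P(G_i = g), g in
#' \{0, 1, 2\}, used as the prior of the single-SNP Bayesian caller.
#' The default (`mode = "hwe"`) computes the smoothed allele-1 frequency
#' p_i = (count_1 + pseudocount) / (N_hap + 2 pseudocount) and returns the
#' Hardy-Weinberg triple ((1-p)^2, 2p(1-p), p^2). `mode = "count"` counts
#' genotypes over consecutive haplotype pairs (rows 1+2, 3+4, ...) with a
#' Laplace pseudocount.
#'
#' @param panel a [haplotype_panel].
#' @param mode `"hwe"` (default) or `"count"`.
#' @param pseudocount nonnegative smoothing count; default 1 so that no
#'   genotype gets a hard zero prior (a zero prior would veto any amount
#'   of read evidence).
#' @return an `n x 3` matrix of priors, rows summing to 1.
#' @export
genotype_prior <- function(panel, mode = c("hwe", "count"), pseudocount = 1) {
  stopifnot(inherits(panel, "haplotype_panel"), pseudocount >= 0)
  mode <- match.arg(mode)
  H <- panel$haplotypes
  N <- nrow(H)
  if (mode == "hwe") {
    p <- (colSums(H) + pseudocount) / (N + 2 * pseudocount)
    pri <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  } else {
    if (N %% 2L != 0L)
      stop("mode = \"count\" needs an even number of haplotypes")
    g <- H[seq(1, N, by = 2), , drop = FALSE] +
         H[seq(2, N, by = 2), , drop = FALSE]
    cnt <- sapply(0:2, function(k) colSums(g == k))
    cnt <- matrix(cnt, ncol = 3) + pseudocount
    pri <- cnt / rowSums(cnt)
  }
  dimnames(pri) <- list(NULL, c("g0", "g1", "g2"))
  pri
}
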