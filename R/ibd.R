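# Method-of-moments IBD estimation from identity-by-state counts, in the
# style of classical genome-wide relatedness screens: observed IBS0/1/2
# proportions are combined with allele-frequency-dependent expectations of
# IBS given IBD (using unbiased small-sample moment corrections) and solved
# for P(IBD = 0/1/2); pihat = P1/2 + P2.

# Unbiased estimators of products of allele frequencies, from allele counts
# x (ALT) and y (REF) out of s total alleles: e.g. E[p^2 q^2] is estimated
# by x(x-1)y(y-1) / [s(s-1)(s-2)(s-3)]. These are the standard
# small-sample correction factors of moment-based IBD estimation.
ibs_expectations <- function(x, s) {
  y <- s - x
  d4 <- s * (s - 1) * (s - 2) * (s - 3)
  d3 <- s * (s - 1) * (s - 2)
  p2q2 <- x * (x - 1) * y * (y - 1) / d4
  p3q <- x * (x - 1) * (x - 2) * y / d4
  pq3 <- x * y * (y - 1) * (y - 2) / d4
  p4 <- x * (x - 1) * (x - 2) * (x - 3) / d4
  q4 <- y * (y - 1) * (y - 2) * (y - 3) / d4
  p2q <- x * (x - 1) * y / d3
  pq2 <- x * y * (y - 1) / d3
  p3 <- x * (x - 1) * (x - 2) / d3
  q3 <- y * (y - 1) * (y - 2) / d3
  list(
    e00 = 2 * p2q2,                 # P(IBS=0 | IBD=0)
    e10 = 4 * p3q + 4 * pq3,        # P(IBS=1 | IBD=0)
    e20 = p4 + q4 + 4 * p2q2,       # P(IBS=2 | IBD=0)
    e11 = 2 * p2q + 2 * pq2,        # P(IBS=1 | IBD=1)
    e21 = p3 + q3 + p2q + pq2       # P(IBS=2 | IBD=1)
  )
}

#' Method-of-moments IBD estimate for one sample pair
#'
#' Counts identity-by-state classes over SNPs where both samples are
#' called, forms the expected IBS-class proportions given IBD state from
#' sample allele frequencies (with small-sample moment corrections), and
#' solves for P(IBD = 0/1/2) by the method of moments. Negative solutions
#' are truncated to zero and the triple renormalized.
#'
#' @param genotypes Dosage matrix (samples x SNPs); allele frequencies are
#'   computed from the full matrix unless `allele_freqs` is given.
#' @param pair Character vector of two sample ids.
#' @param allele_freqs Optional ALT allele frequencies per SNP (e.g. from
#'   founders only); defaults to the sample frequencies of `genotypes`.
#' @param min_snps Minimum number of informative SNPs required.
#' @return A list of class `ibd_estimate`: `pair`, `p0`, `p1`, `p2`,
#'   `pihat`, `n_snps`.
#' @export
ibd_moments <- function(genotypes, pair, allele_freqs = NULL, min_snps = 50L) {
  if (length(pair) != 2L || !all(pair %in% rownames(genotypes))) {
    stop("pair must name two rows of the genotype matrix")
  }
  g1 <- genotypes[pair[1L], ]
  g2 <- genotypes[pair[2L], ]
  n_called <- colSums(!is.na(genotypes))
  if (is.null(allele_freqs)) {
    allele_freqs <- colMeans(genotypes, na.rm = TRUE) / 2
  }
  s <- 2 * n_called
  x <- allele_freqs * s
  use <- !is.na(g1) & !is.na(g2) & s >= 4 & allele_freqs > 0 & allele_freqs < 1
  if (sum(use) < min_snps) {
    stop(sprintf("only %d informative SNPs for pair (%s, %s); need >= %d",
                 sum(use), pair[1L], pair[2L], min_snps))
  }
  ibs <- 2L - abs(g1[use] - g2[use])
  n_ibs <- tabulate(ibs + 1L, nbins = 3L)
  ex <- ibs_expectations(x[use], s[use])
  E00 <- sum(ex$e00); E10 <- sum(ex$e10); E20 <- sum(ex$e20)
  E11 <- sum(ex$e11); E21 <- sum(ex$e21); E22 <- sum(use)
  p0 <- n_ibs[1L] / E00
  p1 <- (n_ibs[2L] - p0 * E10) / E11
  p2 <- (n_ibs[3L] - p0 * E20 - p1 * E21) / E22
  p <- pmin(pmax(c(p0, p1, p2), 0), 1)
  p <- p / sum(p)
  structure(list(pair = pair, p0 = p[1L], p1 = p[2L], p2 = p[3L],
                 pihat = p[2L] / 2 + p[3L], n_snps = sum(use)),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("IBD (%s, %s): P0 = %.3f, P1 = %.3f, P2 = %.3f, pihat = %.3f [%d SNPs]\n",
              x$pair[1L], x$pair[2L], x$p0, x$p1, x$p2, x$pihat, x$n_snps))
  invisible(x)
}

#' Mean pairwise IBD sharing within a sample set
#'
#' Computes [ibd_moments()] for every unordered pair in `sample_ids` and
#' returns the mean and SD of pihat, the summary used to judge whether a
#' group of rare-variant carriers is more closely related to each other
#' than to the rest of the cohort.
#'
#' @inheritParams ibd_moments
#' @param sample_ids At least two sample ids.
#' @return A list: `mean`, `sd`, `n_pairs`, and the per-pair `estimates`
#'   data.frame.
#' @export
mean_pairwise_pihat <- function(genotypes, sample_ids, allele_freqs = NULL,
                                min_snps = 50L) {
  if (length(sample_ids) < 2L) stop("need at least two samples")
  prs <- combn(sample_ids, 2L)
  est <- apply(prs, 2L, function(p) {
    e <- ibd_moments(genotypes, p, allele_freqs, min_snps)
    c(p0 = e$p0, p1 = e$p1, p2 = e$p2, pihat = e$pihat)
  })
  df <- data.frame(id1 = prs[1L, ], id2 = prs[2L, ], t(est),
                   stringsAsFactors = FALSE)
  list(mean = mean(df$pihat), sd = stats::sd(df$pihat),
       n_pairs = nrow(df), estimates = df)
}
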