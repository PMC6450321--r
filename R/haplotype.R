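# Haplotype-background analysis around a focal rare variant: window
# selection, EM estimation of haplotype frequencies from unphased
# genotypes, shared-haplotype detection among carriers, and two-locus LD.

#' Select common SNPs around a focal variant
#'
#' Returns the variant keys of SNPs on the focal variant's chromosome,
#' within +/- `window_kb / 2` of its position, with sample minor allele
#' frequency at least `min_maf`, ordered by position. The focal variant
#' itself is excluded.
#'
#' @param variants Variant table (chrom, pos, variant_key).
#' @param genotypes Dosage matrix used to compute sample MAF (missing
#'   genotypes excluded from denominators).
#' @param focal Variant key of the rare variant of interest.
#' @param window_kb Total window width in kb.
#' @param min_maf Minimum sample minor allele frequency.
#' @return Character vector of variant keys (possibly empty, with a
#'   warning).
#' @export
select_window <- function(variants, genotypes, focal, window_kb = 100,
                          min_maf = 0.05) {
  i <- match(focal, variants$variant_key)
  if (is.na(i)) stop(sprintf("focal variant %s not found", focal))
  half <- window_kb * 1000 / 2
  cand <- variants[variants$chrom == variants$chrom[i] &
                     abs(variants$pos - variants$pos[i]) <= half &
                     variants$variant_key != focal, , drop = FALSE]
  if (nrow(cand)) {
    af <- colMeans(genotypes[, cand$variant_key, drop = FALSE], na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    cand <- cand[!is.na(maf) & maf >= min_maf, , drop = FALSE]
  }
  if (!nrow(cand)) {
    warning(sprintf("no common SNPs within %g kb of %s", window_kb, focal))
    return(character(0))
  }
  cand$variant_key[order(cand$pos)]
}

# Enumerate the ordered haplotype pairs compatible with one multilocus
# genotype vector (0/1/2/NA per site). Haplotypes are encoded as integers
# with bit l set when the ALT allele is carried at site l. Missing sites are
# marginalized by enumerating both alleles on both haplotypes.
compatible_pairs <- function(g) {
  h1 <- 0L; h2 <- 0L
  for (l in seq_along(g)) {
    bit <- bitwShiftL(1L, l - 1L)
    opts <- if (is.na(g[l])) list(c(0L, 0L), c(0L, bit), c(bit, 0L), c(bit, bit))
    else switch(as.character(g[l]),
                `0` = list(c(0L, 0L)),
                `1` = list(c(0L, bit), c(bit, 0L)),
                `2` = list(c(bit, bit)),
                stop("genotype codes must be 0, 1, 2 or NA"))
    n_old <- length(h1)
    n_opt <- length(opts)
    a1 <- vapply(opts, `[`, integer(1), 1L)
    a2 <- vapply(opts, `[`, integer(1), 2L)
    h1 <- rep(h1, times = n_opt) + rep(a1, each = n_old)
    h2 <- rep(h2, times = n_opt) + rep(a2, each = n_old)
  }
  cbind(h1 = h1, h2 = h2)
}

hap_string <- function(code, L) {
  vapply(code, function(h) {
    paste(as.integer(bitwAnd(bitwShiftR(h, 0:(L - 1L)), 1L)), collapse = "")
  }, character(1))
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard EM over unphased multilocus genotypes: the E-step distributes
#' each individual's mass over all haplotype pairs compatible with its
#' genotype in proportion to the product of current haplotype frequencies;
#' the M-step re-estimates frequencies from the expected gamete counts.
#' Missing genotypes are marginalized by enumerating both alleles at the
#' missing sites. Iteration stops when the largest frequency change falls
#' below `tol`. The observed-data log-likelihood is non-decreasing across
#' iterations. Initialization is the linkage-equilibrium
#' product-of-allele-frequency start plus one jittered restart (the run
#' with the higher final log-likelihood is returned); a run whose two
#' starts reach the same likelihood at materially different frequencies
#' is flagged ambiguous rather than broken arbitrarily.
#'
#' @param genotypes Dosage matrix over the window SNPs only (samples x
#'   SNPs, at most 16 SNPs).
#' @param tol Convergence tolerance on the max absolute frequency change.
#' @param max_iter Maximum EM iterations.
#' @param prune_freq Haplotypes below this frequency are pruned from the
#'   returned table (mass renormalized).
#' @return An object of class `haplotype_table`: list with `window`
#'   (variant keys), `haplotypes` (allele strings over the window, `0` =
#'   REF, `1` = ALT), `freqs`, `loglik`, `n_iter`, `converged`,
#'   `ambiguous`, and `loglik_trace`.
#' @export
em_haplotype_frequencies <- function(genotypes, tol = 1e-8, max_iter = 1000L,
                                     prune_freq = 1e-4) {
  L <- ncol(genotypes)
  if (is.null(L) || L < 2L) stop("window must contain at least 2 SNPs")
  if (L > 16L) stop("windows are capped at 16 SNPs to bound enumeration")
  keep <- rowSums(!is.na(genotypes)) > 0L
  g <- genotypes[keep, , drop = FALSE]
  n <- nrow(g)
  if (!n) stop("no individuals with any called genotype in the window")

  # group identical genotype patterns
  pat_key <- apply(g, 1L, function(x) paste(ifelse(is.na(x), ".", x), collapse = ""))
  tab <- table(pat_key)
  patterns <- names(tab)
  wts <- as.numeric(tab)
  pair_sets <- lapply(patterns, function(pk) {
    gv <- suppressWarnings(as.integer(strsplit(chartr(".", "9", pk), "")[[1]]))
    gv[gv == 9L] <- NA_integer_
    compatible_pairs(gv)
  })

  support <- sort(unique(unlist(lapply(pair_sets, as.vector))))
  idx <- function(h) match(h, support)
  pair_idx <- lapply(pair_sets, function(ps) cbind(idx(ps[, 1L]), idx(ps[, 2L])))

  af <- colMeans(g, na.rm = TRUE) / 2
  le_start <- vapply(support, function(h) {
    bits <- as.integer(bitwAnd(bitwShiftR(h, 0:(L - 1L)), 1L))
    prod(ifelse(bits == 1L, af, 1 - af))
  }, numeric(1))
  le_start <- pmax(le_start, 1e-12); le_start <- le_start / sum(le_start)

  run_em <- function(f) {
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      counts <- numeric(length(support))
      ll <- 0
      for (p in seq_along(pair_idx)) {
        pi <- pair_idx[[p]]
        w <- f[pi[, 1L]] * f[pi[, 2L]]
        tot <- sum(w)
        ll <- ll + wts[p] * log(tot)
        w <- w / tot * wts[p]
        for (r in seq_len(nrow(pi))) {
          counts[pi[r, 1L]] <- counts[pi[r, 1L]] + w[r]
          counts[pi[r, 2L]] <- counts[pi[r, 2L]] + w[r]
        }
      }
      trace <- c(trace, ll)
      f_new <- counts / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    list(f = f, loglik = trace[length(trace)], trace = trace,
         n_iter = it, converged = converged)
  }

  fit1 <- run_em(le_start)
  # jittered restart under a locally seeded RNG (caller's stream untouched)
  jitter <- local_runif(length(support), seed = 271828L)
  f2 <- le_start * exp(0.5 * (jitter - 0.5)); f2 <- f2 / sum(f2)
  fit2 <- run_em(f2)
  best <- if (fit2$loglik > fit1$loglik + 1e-9) fit2 else fit1
  # symmetric degeneracy: two starts on the same likelihood at materially
  # different frequencies, or every called genotype heterozygous (the
  # classical all-double-het case, whose MLE ridge has no unique phase)
  ambiguous <- (abs(fit1$loglik - fit2$loglik) < 1e-6 &&
                  max(abs(fit1$f - fit2$f)) > 1e-3) ||
    all(g == 1L | is.na(g))

  f <- best$f
  keep_h <- f >= prune_freq
  f <- f[keep_h] / sum(f[keep_h])
  structure(list(
    window = colnames(genotypes),
    haplotypes = hap_string(support[keep_h], L),
    freqs = unname(f),
    loglik = best$loglik,
    n_iter = best$n_iter,
    converged = best$converged,
    ambiguous = ambiguous,
    loglik_trace = best$trace
  ), class = "haplotype_table")
}

# Uniform draws from a private RNG stream; global RNG state is preserved.
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table over %d SNPs (%d haplotypes, loglik %.3f, %d iterations%s%s)\n",
              length(x$window), length(x$haplotypes), x$loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged",
              if (x$ambiguous) ", AMBIGUOUS" else ""))
  ord <- order(-x$freqs)
  for (i in ord) cat(sprintf("  %s  %.4f\n", x$haplotypes[i], x$freqs[i]))
  invisible(x)
}

#' Haplotypes shared by all carriers of a rare variant
#'
#' For each carrier, the haplotypes receiving posterior phase mass at least
#' `posterior_threshold` under the fitted haplotype table are collected;
#' the result is their intersection across carriers. Case and control
#' frequencies of the shared haplotypes are estimated by separate EM runs
#' restricted to each stratum. A shared haplotype that is common in both
#' strata is the signature of a rare mutation of single ancestral origin
#' riding on an old background.
#'
#' @param table A fitted [em_haplotype_frequencies()] result for the window.
#' @param genotypes Dosage matrix containing the window SNPs for all
#'   samples.
#' @param carriers Sample ids of the rare-variant carriers.
#' @param samples Phenotype data.frame (`sample_id`, `status`).
#' @param posterior_threshold Posterior mass above which a haplotype counts
#'   as present in a carrier (default 0.5).
#' @return A list: `haplotypes` (allele strings shared by all carriers),
#'   `freq_cases`, `freq_controls` (named frequency vectors from the
#'   stratified EM fits), and `n_carriers_used`.
#' @export
shared_haplotype <- function(table, genotypes, carriers, samples,
                             posterior_threshold = 0.5) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!all(carriers %in% rownames(genotypes))) {
    stop("carriers must be rows of the genotype matrix")
  }
  win <- genotypes[, table$window, drop = FALSE]
  L <- length(table$window)
  hap_codes <- strtoi(vapply(table$haplotypes, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1)), base = 2L)

  carrier_sets <- list()
  for (id in carriers) {
    g <- win[id, ]
    if (all(is.na(g))) {
      warning(sprintf("carrier %s has no called genotype in the window; excluded", id))
      next
    }
    pairs <- compatible_pairs(as.integer(g))
    f <- table$freqs[match(pairs, hap_codes)]
    dim(f) <- dim(pairs)
    f[is.na(f)] <- 0  # pruned haplotypes carry no mass
    w <- f[, 1L] * f[, 2L]
    if (sum(w) == 0) {
      warning(sprintf("carrier %s: no compatible phase has positive mass; excluded", id))
      next
    }
    w <- w / sum(w)
    post <- vapply(hap_codes, function(h) {
      sum(w[pairs[, 1L] == h | pairs[, 2L] == h])
    }, numeric(1))
    carrier_sets[[id]] <- table$haplotypes[post >= posterior_threshold]
  }
  if (!length(carrier_sets)) stop("no usable carriers")
  shared <- Reduce(intersect, carrier_sets)

  strat_freq <- function(ids) {
    sub <- win[intersect(ids, rownames(win)), , drop = FALSE]
    fit <- em_haplotype_frequencies(sub)
    out <- stats::setNames(rep(0, length(shared)), shared)
    hit <- match(shared, fit$haplotypes)
    out[!is.na(hit)] <- fit$freqs[hit[!is.na(hit)]]
    out
  }
  cases <- samples$sample_id[samples$status == "case"]
  controls <- samples$sample_id[samples$status == "control"]
  list(haplotypes = shared,
       freq_cases = if (length(shared)) strat_freq(cases) else numeric(0),
       freq_controls = if (length(shared)) strat_freq(controls) else numeric(0),
       n_carriers_used = length(carrier_sets))
}

#' Two-locus linkage disequilibrium
#'
#' Estimates the four two-SNP haplotype frequencies by EM and reports
#' D' and r^2.
#'
#' @param genotypes Dosage matrix with exactly two columns (the two SNPs).
#' @return A list of class `ld_stats`: `d`, `d_prime`, `r2`, and the
#'   haplotype frequency table.
#' @export
ld_stats <- function(genotypes) {
  if (ncol(genotypes) != 2L) stop("ld_stats expects exactly two SNPs")
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  if (any(af %in% c(0, 1)) || any(is.na(af))) {
    stop("both SNPs must be polymorphic")
  }
  fit <- em_haplotype_frequencies(genotypes, prune_freq = 0)
  f <- stats::setNames(rep(0, 4), c("00", "01", "10", "11"))
  f[fit$haplotypes] <- fit$freqs
  p_a <- f[["10"]] + f[["11"]]  # ALT at SNP 1
  p_b <- f[["01"]] + f[["11"]]  # ALT at SNP 2
  d <- f[["11"]] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
  else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d_prime <- if (d_max == 0) 0 else abs(d) / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(list(d = d, d_prime = min(d_prime, 1), r2 = min(r2, 1),
                 freqs = f, p_alt = c(p_a, p_b)),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("Two-locus LD: D = %.4f, D' = %.3f, r2 = %.3f\n",
              x$d, x$d_prime, x$r2))
  invisible(x)
}
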