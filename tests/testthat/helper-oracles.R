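# Independent oracles and fixture builders. Every oracle here re-derives
# its quantity from first principles by a different route than the package
# implementation (brute-force enumeration, grid search, direct simulation).

# ---- brute-force case-only filter oracle -----------------------------------
# Direct enumeration of the filter definition over a merged counts +
# annotation table; no shared code with apply_scheme().
oracle_filter <- function(counts, annotations, impacts, min_case,
                          max_control = 0L, gene_list = NULL,
                          min_distinct = NULL, max_pop_af = NULL) {
  keep <- character(0)
  af_cols <- grep("^af_", names(annotations), value = TRUE)
  for (i in seq_len(nrow(counts))) {
    key <- counts$variant_key[i]
    a <- annotations[annotations$variant_key == key, , drop = FALSE]
    if (nrow(a) == 0L) next
    ok <- a$impact[1L] %in% impacts &&
      counts$n_case_carriers[i] >= min_case &&
      counts$n_control_carriers[i] <= max_control
    if (ok && !is.null(gene_list)) ok <- a$gene[1L] %in% gene_list
    if (ok && !is.null(max_pop_af)) {
      for (cl in af_cols) {
        v <- a[[cl]][1L]
        if (!is.na(v) && v > max_pop_af) ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, key)
  }
  if (!is.null(min_distinct)) {
    genes <- annotations$gene[match(keep, annotations$variant_key)]
    good <- names(table(genes))[table(genes) >= min_distinct]
    keep <- keep[genes %in% good]
  }
  sort(keep)
}

# ---- exhaustive-simplex oracle for haplotype frequencies -------------------
# Likelihood built by checking all ordered pairs of the 2^L haplotypes
# against each distinct genotype pattern (expand.grid representation, no
# shared code with the package EM), maximized by a simplex grid search
# polished with multi-start optim on softmax parameters.
oracle_hap_patterns <- function(geno) {
  L <- ncol(geno)
  haps <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
  nh <- nrow(haps)
  key <- apply(geno, 1L, function(g) paste(ifelse(is.na(g), ".", g), collapse = ""))
  tab <- table(key)
  pairs <- lapply(names(tab), function(k) {
    g <- suppressWarnings(as.integer(strsplit(chartr(".", "9", k), "")[[1]]))
    g[g == 9L] <- NA
    prs <- NULL
    for (a in seq_len(nh)) {
      for (b in seq_len(nh)) {
        s <- haps[a, ] + haps[b, ]
        if (all(is.na(g) | s == g)) prs <- rbind(prs, c(a, b))
      }
    }
    prs
  })
  hap_names <- apply(haps, 1L, paste, collapse = "")
  list(pairs = pairs, w = as.numeric(tab), nh = nh, hap_names = hap_names)
}

oracle_hap_loglik <- function(pp, f) {
  sum(vapply(seq_along(pp$pairs), function(i) {
    prs <- pp$pairs[[i]]
    pp$w[i] * log(sum(f[prs[, 1L]] * f[prs[, 2L]]))
  }, numeric(1)))
}

oracle_hap_mle <- function(geno, grid_units = 8L) {
  pp <- oracle_hap_patterns(geno)
  nh <- pp$nh
  comp <- function(units, cells) {
    if (cells == 1L) return(matrix(units, 1L, 1L))
    do.call(rbind, lapply(0:units, function(u) cbind(u, comp(units - u, cells - 1L))))
  }
  grid <- comp(grid_units, nh) / grid_units
  lls <- apply(grid, 1L, function(f) {
    f <- pmax(f, 1e-12); f <- f / sum(f)
    oracle_hap_loglik(pp, f)
  })
  top <- order(lls, decreasing = TRUE)[seq_len(min(10L, nrow(grid)))]
  best <- NULL; best_ll <- -Inf
  for (t in top) {
    start <- log(pmax(grid[t, ], 1e-4))
    op <- optim(start, function(theta) {
      f <- exp(theta - max(theta)); f <- f / sum(f)
      -oracle_hap_loglik(pp, f)
    }, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    f <- exp(op$par - max(op$par)); f <- f / sum(f)
    if (-op$value > best_ll) { best_ll <- -op$value; best <- f }
  }
  list(freqs = setNames(best, pp$hap_names), loglik = best_ll)
}

# Map an em_haplotype_frequencies() result onto the full 2^L-vector used by
# the oracle (pruned haplotypes get 0).
em_full_freqs <- function(fit) {
  L <- length(fit$window)
  hap_names <- apply(as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE],
                     1L, paste, collapse = "")
  f <- setNames(rep(0, 2^L), hap_names)
  f[fit$haplotypes] <- fit$freqs
  f
}

# ---- exhaustive hypergeometric oracle --------------------------------------
# P(X >= obs) by explicit combinatorial enumeration of the tail terms; for
# tiny universes, additionally verifiable by combn() subset counting.
oracle_hyper_tail <- function(obs, n_annotated, universe, k_draw) {
  num <- 0
  for (x in obs:min(n_annotated, k_draw)) {
    num <- num + choose(n_annotated, x) * choose(universe - n_annotated, k_draw - x)
  }
  num / choose(universe, k_draw)
}

oracle_hyper_combn <- function(obs, n_annotated, universe, k_draw) {
  # label genes 1..universe; 1..n_annotated are in the pathway
  subsets <- combn(universe, k_draw)
  hits <- colSums(subsets <= n_annotated)
  mean(hits >= obs)
}

# ---- direct cousin-pair sharing oracle -------------------------------------
# Simulates allele transmission along the explicit grandparent->parent->child
# paths (no pedigree machinery) and returns the count of variants carried by
# both cousins.
oracle_cousin_shared <- function(founder_freqs) {
  m <- length(founder_freqs)
  draw <- function() cbind(rbinom(m, 1L, founder_freqs), rbinom(m, 1L, founder_freqs))
  pick <- function(g) ifelse(rbinom(m, 1L, 0.5) == 1L, g[, 1L], g[, 2L])
  gp <- draw(); gm <- draw()               # shared grandparents
  p1 <- cbind(pick(gp), pick(gm))          # two sib parents
  p2 <- cbind(pick(gp), pick(gm))
  s1 <- draw(); s2 <- draw()               # unrelated spouses
  c1 <- pick(p1) + pick(s1)
  c2 <- pick(p2) + pick(s2)
  sum(c1 >= 1L & c2 >= 1L)
}

# ---- small fixture builders ------------------------------------------------
write_test_vcf <- function(lines, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines
  ), path)
  path
}

toy_samples <- function(n_case, n_control) {
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n_case + n_control)),
    status = c(rep("case", n_case), rep("control", n_control)),
    stringsAsFactors = FALSE
  )
}

# random toy cohort for filter-oracle equivalence: counts are generated
# directly (not via genotypes) to cover the threshold boundaries densely
random_counts_annotations <- function(n_variants, n_case, n_control, seed) {
  set.seed(seed)
  keys <- sprintf("1:%d:A:T", seq_len(n_variants) * 100L)
  genes <- sample(sprintf("G%02d", 1:12), n_variants, replace = TRUE)
  counts <- data.frame(
    variant_key = keys,
    n_case_carriers = sample(0:12, n_variants, replace = TRUE),
    n_control_carriers = sample(0:3, n_variants, replace = TRUE,
                                prob = c(0.6, 0.2, 0.1, 0.1)),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    variant_key = keys, gene = genes,
    consequence = sample(c("stop_gained", "missense_variant", "synonymous_variant"),
                         n_variants, replace = TRUE),
    impact = sample(c("HIGH", "MODERATE", "LOW"), n_variants, replace = TRUE),
    af_nfe = round(runif(n_variants, 0, 0.03), 5),
    af_afr = round(runif(n_variants, 0, 0.03), 5),
    stringsAsFactors = FALSE
  )
  list(counts = counts, annotations = ann)
}

# two-cousin pedigree (shared grandparents gp/gm) used across family tests
cousin_pedigree <- function() {
  data.frame(
    family_id = "F1",
    id = c("gp", "gm", "p1", "p2", "s1", "s2", "c1", "c2"),
    father = c(NA, NA, "gp", "gp", NA, NA, "p1", "p2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "s1", "s2"),
    sex = c("1", "2", "1", "1", "2", "2", "1", "1"),
    affected = c("unknown", "unknown", "no", "no", "no", "no", "yes", "yes"),
    genotyped = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
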