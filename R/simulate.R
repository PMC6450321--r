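# Synthetic case-control exome-like cohorts with the statistical structure
# the case-only pipeline assumes: subpopulation divergence under a
# Balding-Nichols model, Hardy-Weinberg genotypes within subpopulation,
# cryptic relatedness by gamete dropping, common-SNP haplotype backgrounds,
# and planted case-only deleterious variants with exact carrier counts.

#' Specify a planted rare variant
#'
#' Describes one deleterious variant to plant into a simulated cohort with
#' exact carrier counts, optionally on a designated shared haplotype
#' background and/or restricted to one subpopulation. Default haplotype
#' background frequencies (15% in cases, 14% in controls) reflect a common
#' haplotype on which a rare mutation of single ancestral origin typically
#' rides.
#'
#' @param gene Gene symbol for the annotation.
#' @param impact `"HIGH"` or `"MODERATE"`.
#' @param case_carriers Exact number of case carriers.
#' @param control_carriers Exact number of control carriers (default 0).
#' @param on_shared_haplotype When `TRUE`, every carrier receives one copy of
#'   a designated common haplotype over the surrounding SNP window.
#' @param subpop Optional subpopulation label (`"P1"`, ...) restricting
#'   carriers.
#' @param hap_freq_cases,hap_freq_controls Background frequency of the
#'   designated haplotype among case and control gametes.
#' @param pop_af Reference-population allele frequency recorded in the
#'   annotation (default 5e-4, a typically "rare" value).
#' @param homozygous Plant carriers as homozygotes instead of heterozygotes.
#' @return A list of class `planted_variant`.
#' @export
planted_variant <- function(gene, impact = c("MODERATE", "HIGH"),
                            case_carriers, control_carriers = 0L,
                            on_shared_haplotype = FALSE, subpop = NULL,
                            hap_freq_cases = 0.15, hap_freq_controls = 0.14,
                            pop_af = 5e-4, homozygous = FALSE) {
  impact <- match.arg(impact)
  stopifnot(case_carriers >= 0, control_carriers >= 0)
  structure(list(
    gene = gene, impact = impact,
    case_carriers = as.integer(case_carriers),
    control_carriers = as.integer(control_carriers),
    on_shared_haplotype = on_shared_haplotype, subpop = subpop,
    hap_freq_cases = hap_freq_cases, hap_freq_controls = hap_freq_controls,
    pop_af = pop_af, homozygous = homozygous
  ), class = "planted_variant")
}

#' Configure a synthetic cohort
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_background_snps Number of common background SNPs.
#' @param n_subpops Number of subpopulations.
#' @param fst Balding-Nichols divergence parameter in (0, 1); subpopulation
#'   allele frequencies are drawn from
#'   `Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)` around the ancestral frequency
#'   `p`.
#' @param maf_range Range of ancestral background allele frequencies,
#'   within (0, 0.5].
#' @param planted List of [planted_variant()] specifications.
#' @param related_pairs Named integer vector of cryptic-relative pair counts,
#'   e.g. `c(full_sib = 2, duplicate = 1)`; names from
#'   `duplicate`, `parent_offspring`, `full_sib`, `first_cousin`.
#' @param window_kb Width of the haplotype window (kb) placed around each
#'   planted variant with a shared background.
#' @param snp_spacing_bp Physical spacing of background SNPs (uniform).
#' @param age_case,age_control Mean and SD of the age distributions; the
#'   defaults (76.4/9.3 for cases, 86.5/4.5 for controls) mimic a
#'   late-onset dementia cohort where controls must survive dementia-free
#'   to an older age, reproducing that confounding direction.
#' @param prop_female_case,prop_female_control Probability of female sex.
#' @param centers Sequencing-center labels sampled uniformly.
#' @param seed Integer seed; the entire simulation is a deterministic
#'   function of the config including this seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases, n_controls, n_background_snps = 2000L,
                              n_subpops = 1L, fst = 0.1,
                              maf_range = c(0.05, 0.5),
                              planted = list(), related_pairs = integer(0),
                              window_kb = 100, snp_spacing_bp = 1000L,
                              age_case = c(76.4, 9.3),
                              age_control = c(86.5, 4.5),
                              prop_female_case = 0.57,
                              prop_female_control = 0.59,
                              centers = c("C1", "C2", "C3"), seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_background_snps >= 1,
            n_subpops >= 1, fst > 0, fst < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], window_kb > 0)
  if (inherits(planted, "planted_variant")) planted <- list(planted)
  for (pv in planted) {
    stopifnot(inherits(pv, "planted_variant"))
    if (pv$case_carriers > n_cases || pv$control_carriers > n_controls) {
      stop(sprintf("planted variant in %s: carriers exceed cohort size", pv$gene))
    }
  }
  rel_names <- c("duplicate", "parent_offspring", "full_sib", "first_cousin")
  if (length(related_pairs) && !all(names(related_pairs) %in% rel_names)) {
    stop(sprintf("related_pairs names must be among: %s",
                 paste(rel_names, collapse = ", ")))
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_background_snps = as.integer(n_background_snps),
    n_subpops = as.integer(n_subpops), fst = fst, maf_range = maf_range,
    planted = planted, related_pairs = related_pairs,
    window_kb = window_kb, snp_spacing_bp = as.integer(snp_spacing_bp),
    age_case = age_case, age_control = age_control,
    prop_female_case = prop_female_case,
    prop_female_control = prop_female_control,
    centers = centers, seed = as.integer(seed)
  ), class = "simulation_config")
}

# One meiosis per SNP: pick one allele at random from each of two parental
# gametes (no linkage between background SNPs; physical distance only
# matters for window selection).
meiosis <- function(g1, g2) {
  pick <- rbinom(length(g1), 1L, 0.5) == 1L
  ifelse(pick, g1, g2)
}

#' Simulate a structured case-control cohort with planted ground truth
#'
#' Background SNP allele frequencies are drawn per subpopulation under a
#' Balding-Nichols model; genotypes are Hardy-Weinberg within
#' subpopulation; cryptic relative pairs are produced by gamete dropping
#' from shared founders; each planted variant receives exactly its
#' specified carrier counts; carriers of a variant marked
#' `on_shared_haplotype` all receive one designated common haplotype over
#' the surrounding window. Ancestry principal components are computed from
#' the background genotypes and stored with the samples.
#'
#' @param config A [simulation_config()].
#' @return A list of class `cohort_sim` with elements `variants`,
#'   `genotypes` (dosage matrix), `annotations`, `samples`, `truth` (planted
#'   variants with their designated haplotypes, relative pairs, and latent
#'   subpopulation allele frequencies), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  m <- config$n_background_snps
  K <- config$n_subpops
  ids <- sprintf("S%05d", seq_len(n))
  status <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  subpop <- sample.int(K, n, replace = TRUE)

  # Balding-Nichols background frequencies
  p0 <- runif(m, config$maf_range[1], config$maf_range[2])
  p_sub <- matrix(p0, m, K)
  if (K > 1L) {
    a <- (1 - config$fst) / config$fst
    for (k in seq_len(K)) {
      p_sub[, k] <- pmin(pmax(rbeta(m, p0 * a, (1 - p0) * a), 1e-4), 1 - 1e-4)
    }
  }

  # gametes: two n x m haplotype matrices
  gam1 <- matrix(0L, n, m)
  gam2 <- matrix(0L, n, m)
  for (k in seq_len(K)) {
    rows <- which(subpop == k)
    pk <- p_sub[, k]
    gam1[rows, ] <- matrix(rbinom(length(rows) * m, 1L, rep(pk, each = length(rows))),
                           length(rows), m)
    gam2[rows, ] <- matrix(rbinom(length(rows) * m, 1L, rep(pk, each = length(rows))),
                           length(rows), m)
  }

  # cryptic relatedness by gamete dropping from shared founders
  rel_rows <- list()
  used <- logical(n)
  pop_gamete <- function(k) rbinom(m, 1L, p_sub[, k])
  rels <- config$related_pairs
  for (rel in names(rels)) {
    for (cnt in seq_len(rels[[rel]])) {
      k <- sample.int(K, 1L)
      avail <- which(!used & subpop == k)
      if (length(avail) < 2L) stop("not enough unrelated samples left to form related pairs")
      pair <- sample(avail, 2L)
      used[pair] <- TRUE
      i <- pair[1L]; j <- pair[2L]
      if (rel == "duplicate") {
        gam1[j, ] <- gam1[i, ]; gam2[j, ] <- gam2[i, ]
      } else if (rel == "parent_offspring") {
        gam1[j, ] <- meiosis(gam1[i, ], gam2[i, ])
        gam2[j, ] <- pop_gamete(k)
      } else if (rel == "full_sib") {
        fa1 <- pop_gamete(k); fa2 <- pop_gamete(k)
        mo1 <- pop_gamete(k); mo2 <- pop_gamete(k)
        gam1[i, ] <- meiosis(fa1, fa2); gam2[i, ] <- meiosis(mo1, mo2)
        gam1[j, ] <- meiosis(fa1, fa2); gam2[j, ] <- meiosis(mo1, mo2)
      } else if (rel == "first_cousin") {
        gp1 <- pop_gamete(k); gp2 <- pop_gamete(k)
        gm1 <- pop_gamete(k); gm2 <- pop_gamete(k)
        par1 <- list(meiosis(gp1, gp2), meiosis(gm1, gm2))
        par2 <- list(meiosis(gp1, gp2), meiosis(gm1, gm2))
        gam1[i, ] <- meiosis(par1[[1L]], par1[[2L]]); gam2[i, ] <- pop_gamete(k)
        gam1[j, ] <- meiosis(par2[[1L]], par2[[2L]]); gam2[j, ] <- pop_gamete(k)
      }
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[j], relationship = rel,
        stringsAsFactors = FALSE)
    }
  }

  # planted variants with exact carrier counts
  bg_pos <- seq_len(m) * config$snp_spacing_bp
  n_pl <- length(config$planted)
  planted_cols <- list()
  planted_rows <- list()
  is_case <- status == "case"
  for (j in seq_len(n_pl)) {
    pv <- config$planted[[j]]
    anchor <- max(1L, round(m * j / (n_pl + 1)))
    pos <- bg_pos[anchor] + config$snp_spacing_bp %/% 2L
    eligible_case <- if (is.null(pv$subpop)) which(is_case) else
      which(is_case & paste0("P", subpop) == pv$subpop)
    eligible_ctrl <- if (is.null(pv$subpop)) which(!is_case) else
      which(!is_case & paste0("P", subpop) == pv$subpop)
    if (pv$case_carriers > length(eligible_case) ||
        pv$control_carriers > length(eligible_ctrl)) {
      stop(sprintf("planted variant in %s: carriers exceed eligible subpopulation size",
                   pv$gene))
    }
    carriers <- c(if (pv$case_carriers) sample(eligible_case, pv$case_carriers),
                  if (pv$control_carriers) sample(eligible_ctrl, pv$control_carriers))
    dose <- integer(n)
    dose[carriers] <- if (pv$homozygous) 2L else 1L

    hap_str <- NA_character_
    window_keys <- NA_character_
    if (pv$on_shared_haplotype) {
      half <- config$window_kb * 1000 / 2
      W <- which(abs(bg_pos - pos) <= half)
      if (!length(W)) stop("shared-haplotype window contains no background SNPs")
      H <- rbinom(length(W), 1L, p0[W])
      # regenerate the window for everyone from a limited haplotype pool:
      # regional LD over tens of kb leaves only a handful of common
      # haplotypes, so each gamete is the designated haplotype with the
      # stratum frequency and otherwise one of a small set of background
      # haplotypes with Dirichlet-distributed frequencies
      n_pool <- 6L
      pool <- matrix(rbinom(n_pool * length(W), 1L, rep(p0[W], each = n_pool)),
                     n_pool, length(W))
      for (b in seq_len(n_pool)) {  # keep pool haplotypes distinct from H
        if (all(pool[b, ] == H)) pool[b, 1L] <- 1L - pool[b, 1L]
      }
      w_pool <- stats::rgamma(n_pool, 1); w_pool <- w_pool / sum(w_pool)
      fr <- ifelse(is_case, pv$hap_freq_cases, pv$hap_freq_controls)
      window_gametes <- function() {
        take_h <- rbinom(n, 1L, fr) == 1L
        block <- pool[sample.int(n_pool, n, replace = TRUE, prob = w_pool), ,
                      drop = FALSE]
        block[take_h, ] <- matrix(H, sum(take_h), length(W), byrow = TRUE)
        block
      }
      gam1[, W] <- window_gametes()
      gam2[, W] <- window_gametes()
      gam1[carriers, W] <- matrix(H, length(carriers), length(W), byrow = TRUE)
      hap_str <- paste(H, collapse = "")
      window_keys <- paste(variant_key("1", bg_pos[W], "A", "C"), collapse = ",")
    }
    key <- variant_key("1", pos, "A", "T")
    planted_cols[[key]] <- dose
    planted_rows[[j]] <- data.frame(
      chrom = "1", pos = pos, id = sprintf("pv%d", j), ref = "A", alt = "T",
      variant_key = key, gene = pv$gene, impact = pv$impact,
      case_carriers = pv$case_carriers, control_carriers = pv$control_carriers,
      on_shared_haplotype = pv$on_shared_haplotype,
      subpop = pv$subpop %||% NA_character_,
      shared_haplotype = hap_str, window_keys = window_keys,
      pop_af = pv$pop_af, stringsAsFactors = FALSE)
  }

  # assemble variant table and dosage matrix, sorted by position
  bg_var <- new_variant_table("1", bg_pos, sprintf("bg%d", seq_len(m)), "A", "C")
  geno_bg <- gam1 + gam2
  colnames(geno_bg) <- bg_var$variant_key
  if (n_pl) {
    pl <- do.call(rbind, planted_rows)
    pl_var <- new_variant_table(pl$chrom, pl$pos, pl$id, pl$ref, pl$alt)
    variants <- rbind(bg_var, pl_var)
    geno <- cbind(geno_bg, do.call(cbind, planted_cols))
  } else {
    pl <- NULL
    variants <- bg_var
    geno <- geno_bg
  }
  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  geno <- geno[, ord, drop = FALSE]
  rownames(geno) <- ids

  # annotations: background SNPs are intergenic MODIFIER with the ancestral
  # frequency as reference AF; planted variants get their spec's gene/impact
  ann_bg <- data.frame(
    variant_key = bg_var$variant_key, gene = sprintf("BG%04d", seq_len(m)),
    consequence = "intergenic_variant", impact = "MODIFIER",
    af_ref = round(p0, 6), stringsAsFactors = FALSE)
  annotations <- ann_bg
  if (n_pl) {
    ann_pl <- data.frame(
      variant_key = pl$variant_key, gene = pl$gene,
      consequence = ifelse(pl$impact == "HIGH", "stop_gained", "missense_variant"),
      impact = pl$impact, af_ref = pl$pop_af, stringsAsFactors = FALSE)
    annotations <- rbind(annotations, ann_pl)
  }

  # covariates and ancestry principal components
  age_mu <- ifelse(is_case, config$age_case[1], config$age_control[1])
  age_sd <- ifelse(is_case, config$age_case[2], config$age_control[2])
  pf <- ifelse(is_case, config$prop_female_case, config$prop_female_control)
  samples <- data.frame(
    sample_id = ids, status = status,
    sex = ifelse(rbinom(n, 1L, pf) == 1L, "female", "male"),
    age = round(rnorm(n, age_mu, age_sd), 1),
    center = sample(config$centers, n, replace = TRUE),
    cluster = paste0("P", subpop), stringsAsFactors = FALSE)
  k_pc <- min(2L, n - 1L)
  pcs <- compute_pcs(geno_bg, k_pc)
  for (d in seq_len(k_pc)) samples[[paste0("pc", d)]] <- pcs[, d]

  truth <- list(
    planted = pl,
    relationships = if (length(rel_rows)) do.call(rbind, rel_rows) else
      data.frame(id1 = character(0), id2 = character(0),
                 relationship = character(0), stringsAsFactors = FALSE),
    subpop_freqs = p_sub, ancestral_freqs = p0)

  structure(list(variants = variants, genotypes = geno,
                 annotations = annotations, samples = samples,
                 truth = truth, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases, %d controls, %d variants (%d planted)\n",
              x$config$n_cases, x$config$n_controls, nrow(x$variants),
              length(x$config$planted)))
  cat(sprintf("  subpopulations: %d (fst = %g); related pairs: %d; seed %d\n",
              x$config$n_subpops, x$config$fst,
              nrow(x$truth$relationships), x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to standard files
#'
#' Emits `cohort.vcf`, `annotations.tsv`, `phenotypes.tsv`, `pedigree.ped`
#' (relative pairs as two-member families with unknown parents),
#' and `truth.tsv` into a directory. Every file records the simulation seed
#' in a comment/header line.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- sprintf("seed=%d", sim$config$seed)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ann = file.path(dir, "annotations.tsv"),
             phe = file.path(dir, "phenotypes.tsv"),
             ped = file.path(dir, "pedigree.ped"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$variants, sim$genotypes, paths["vcf"],
            header_extra = sprintf("##caseonly_%s", seed_line))
  write_tsv_commented <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# caseonly %s %s",
                       as.character(utils::packageVersion("caseonly")), seed_line), con)
    if (is.null(df) || !nrow(df)) df <- data.frame(empty = logical(0))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_commented(sim$annotations, paths["ann"])
  write_tsv_commented(sim$samples, paths["phe"])
  write_tsv_commented(sim$truth$planted, paths["truth"])
  rel <- sim$truth$relationships
  ped_lines <- character(0)
  if (nrow(rel)) {
    for (r in seq_len(nrow(rel))) {
      fam <- sprintf("F%03d", r)
      ped_lines <- c(ped_lines,
                     paste(fam, rel$id1[r], 0, 0, 0, 2, 1, sep = "\t"),
                     paste(fam, rel$id2[r], 0, 0, 0, 2, 1, sep = "\t"))
    }
  }
  writeLines(ped_lines, paths["ped"])
  invisible(paths)
}

#' Drop genotypes through a pedigree
#'
#' Founder genotypes are drawn in Hardy-Weinberg proportions from
#' `founder_freqs`; every non-founder receives one allele chosen at random
#' from each parent at each site (Mendelian transmission, no mutation).
#' Optionally one extra variant is planted as a heterozygote in a named
#' founder and transmitted like any other allele.
#'
#' @param pedigree A single-family pedigree data.frame as from [read_ped()].
#' @param founder_freqs Numeric vector of allele frequencies (optionally
#'   named by variant key).
#' @param planted Optional list `list(founder = "<id>", variant_key = "...")`
#'   planting one heterozygous variant in that founder.
#' @return Dosage matrix (members x variants) with individual ids as row
#'   names.
#' @export
simulate_pedigree_genotypes <- function(pedigree, founder_freqs, planted = NULL) {
  if (length(unique(pedigree$family_id)) != 1L) {
    stop("pedigree must contain a single family")
  }
  ord <- pedigree_order(pedigree)
  m <- length(founder_freqs)
  keys <- names(founder_freqs)
  if (is.null(keys)) keys <- variant_key("1", seq_len(m) * 1000L, "A", "C")
  n_extra <- if (is.null(planted)) 0L else 1L
  if (n_extra) {
    if (!planted$founder %in% pedigree$id) {
      stop(sprintf("planted founder %s not in pedigree", planted$founder))
    }
    keys <- c(keys, planted$variant_key %||% variant_key("1", (m + 1L) * 1000L, "G", "A"))
  }
  gam <- list()
  for (id in ord) {
    row <- pedigree[pedigree$id == id, ]
    g <- matrix(0L, 2L, m + n_extra)
    founder <- is.na(row$father) && is.na(row$mother)
    if (founder) {
      g[1L, seq_len(m)] <- rbinom(m, 1L, founder_freqs)
      g[2L, seq_len(m)] <- rbinom(m, 1L, founder_freqs)
      if (n_extra && id == planted$founder) g[1L, m + 1L] <- 1L
    } else {
      for (hap in 1:2) {
        par <- if (hap == 1L) row$father else row$mother
        if (is.na(par)) {  # single known parent: other gamete from population
          g[hap, seq_len(m)] <- rbinom(m, 1L, founder_freqs)
        } else {
          g[hap, ] <- meiosis(gam[[par]][1L, ], gam[[par]][2L, ])
        }
      }
    }
    gam[[id]] <- g
  }
  out <- t(vapply(pedigree$id, function(id) as.integer(colSums(gam[[id]])),
                  integer(m + n_extra)))
  colnames(out) <- keys
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
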