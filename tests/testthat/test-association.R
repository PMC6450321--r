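test_that("pooled-variance Z statistic matches direct evaluation and is antisymmetric", {
  # (2, 10, 0, 10): phat = 0.1, se = sqrt(0.1 * 0.9 * 0.2), z = 0.2 / se
  r <- two_proportion_z(2, 10, 0, 10)
  expect_equal(r$z, 0.2 / sqrt(0.1 * 0.9 * 0.2), tolerance = 1e-12)
  expect_equal(round(r$z, 3), 1.491)
  expect_equal(two_proportion_z(5, 100, 5, 100)$z, 0)
  # swapping the groups negates z
  a <- two_proportion_z(8, 358, 0, 337)
  b <- two_proportion_z(0, 337, 8, 358)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  # no carriers anywhere leaves no variance
  d <- two_proportion_z(0, 50, 0, 60)
  expect_true(d$degenerate)
  expect_equal(d$z, 0)
})

make_burden_cohort <- function() {
  ann <- data.frame(
    variant_key = c("1:1:A:T", "1:2:A:T", "1:3:A:T", "1:4:A:T"),
    gene = c("PSEN1", "PSEN1", "OTHER", "PSEN1"),
    consequence = "missense_variant",
    impact = c("HIGH", "MODERATE", "HIGH", "LOW"),
    stringsAsFactors = FALSE)
  geno <- matrix(0L, 10, 4,
                 dimnames = list(sprintf("S%03d", 1:10), ann$variant_key))
  geno[1, 1] <- 1L; geno[1, 2] <- 1L   # two qualifying hets in one sample
  geno[2, 3] <- 1L                     # off-gene-set variant
  geno[3, 4] <- 1L                     # LOW impact
  list(geno = geno, ann = ann)
}

test_that("CMC collapse counts qualifying minor alleles per sample", {
  x <- make_burden_cohort()
  b <- cmc_collapse(x$geno, x$ann, gene_set = "PSEN1", maf_max = 0.2)
  expect_equal(unname(b[1]), 2)              # count mode sums dosages
  expect_equal(sum(b[-1]), 0)                # off-set and LOW never qualify
  bi <- cmc_collapse(x$geno, x$ann, gene_set = "PSEN1", maf_max = 0.2,
                     mode = "indicator")
  expect_equal(unname(bi[1]), 1)
  expect_error(cmc_collapse(x$geno, x$ann, gene_set = "NOPE"), "no qualifying")
})

test_that("the MAF cutoff excludes common variants and is inert without them", {
  set.seed(33)
  n <- 200L
  geno <- cbind(rbinom(n, 2, 0.03),            # MAF ~0.03
                c(rep(1L, 4), rep(0L, n - 4)))  # rare
  dimnames(geno) <- list(sprintf("S%03d", 1:n), c("1:1:A:T", "1:2:A:T"))
  ann <- data.frame(variant_key = colnames(geno), gene = "G",
                    consequence = "missense_variant", impact = "MODERATE",
                    stringsAsFactors = FALSE)
  b_strict <- cmc_collapse(geno, ann, "G", maf_max = 0.01)
  expect_equal(attr(b_strict, "qualifying"), "1:2:A:T")
  b_loose <- cmc_collapse(geno, ann, "G", maf_max = 0.05)
  expect_equal(length(attr(b_loose, "qualifying")), 2L)
  # with no variants in (0.01, 0.02], widening the cutoff changes nothing
  b2 <- cmc_collapse(geno, ann, "G", maf_max = 0.02)
  expect_identical(as.numeric(b2), as.numeric(b_strict))
})

test_that("burden regression rejects degenerate inputs and flags separation", {
  samples <- data.frame(sample_id = sprintf("S%03d", 1:40),
                        status = rep(c("case", "control"), each = 20),
                        stringsAsFactors = FALSE)
  expect_error(burden_logistic(setNames(rep(0, 40), samples$sample_id), samples),
               "no variation")
  # burden present in every case and no control: complete separation
  b <- setNames(c(rep(1, 20), rep(0, 20)), samples$sample_id)
  fit <- burden_logistic(b, samples, covariates = character(0), n_pcs = 0)
  expect_true(fit$firth)
  expect_true(is.finite(fit$beta) && is.finite(fit$se))
  expect_gt(fit$beta, 0)
})

test_that("burden regression recovers a planted log-odds ratio", {
  set.seed(14)
  reps <- 60L
  betas <- ses <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 800L
    burden <- rpois(n, 0.5)
    age <- rnorm(n, 80, 8)
    eta <- -0.2 + 0.3 * burden + 0.02 * (age - 80)
    status <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "case", "control")
    samples <- data.frame(sample_id = sprintf("S%04d", 1:n), status = status,
                          age = age, stringsAsFactors = FALSE)
    fit <- burden_logistic(setNames(burden, samples$sample_id), samples,
                           covariates = "age", n_pcs = 0)
    betas[r] <- fit$beta; ses[r] <- fit$se
  }
  se_mean <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - 0.3), 2 * se_mean)
  # reported cumulative counts split the qualifying alleles by status
  expect_true(fit$n_carrier_variants_cases + fit$n_carrier_variants_controls ==
                sum(burden))
})

test_that("hypergeometric enrichment matches exhaustive enumeration on small universes", {
  # closed case: network 5, pathway 3, universe 10, observed 3 -> 21/252
  paths <- list(p = paste0("G", 1:3))
  net <- paste0("G", 1:5)
  row <- fisher_enrichment(net, paths, universe_size = 10)
  expect_equal(row$p_unadjusted, 21 / 252, tolerance = 1e-12)
  expect_equal(row$p_unadjusted, oracle_hyper_combn(3, 3, 10, 5), tolerance = 1e-12)
  # randomized small cases against the combinatorial tail oracle
  set.seed(99)
  for (i in 1:20) {
    universe <- sample(20:50, 1)
    m <- sample(3:12, 1)
    k <- sample(3:15, 1)
    obs <- sample(0:min(m, k), 1)
    pathways <- list(x = paste0("G", seq_len(m)))
    network <- c(sprintf("G%d", seq_len(obs)),
                 sprintf("H%d", seq_len(k - obs)))
    got <- fisher_enrichment(network, pathways, universe_size = universe)
    expect_equal(got$p_unadjusted, oracle_hyper_tail(obs, m, universe, k),
                 tolerance = 1e-12)
  }
})

test_that("expected counts, fold enrichment and empty overlap behave as defined", {
  paths <- list(hit = paste0("G", 1:40), empty = paste0("Z", 1:10))
  net <- c(paste0("G", 1:20), paste0("N", 1:10))
  out <- fisher_enrichment(net, paths, universe_size = 20000)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$fold[i] * out$expected[i], out$n_observed[i],
                 tolerance = 1e-12)
  }
  empty <- out[out$pathway == "empty", ]
  expect_equal(empty$p_unadjusted, 1)
  expect_equal(empty$fold, 0)
  expect_true(all(out$fdr >= 0 & out$fdr <= 1))
})

test_that("BH adjustment reproduces the hand-evaluated step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(4)
  p <- runif(50)
  adj <- bh_fdr(p)
  # step-up evaluated directly from the definition
  ord <- order(p)
  manual <- rev(cummin(rev(p[ord] * 50 / seq_len(50))))
  expect_equal(adj[ord], pmin(manual, 1))
  expect_true(all(diff(adj[ord]) >= 0))
})

test_that("principal components separate simulated subpopulations", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 100, n_controls = 100, n_background_snps = 2000,
    n_subpops = 2, fst = 0.1, seed = 121))
  pcs <- compute_pcs(sim$genotypes, 2)
  labels <- assign_cluster(pcs, "kmeans", list(k = 2, seed = 42))
  truth <- sim$samples$cluster
  agree <- max(mean(labels == paste0("C", as.integer(factor(truth)))),
               mean(labels == paste0("C", 3 - as.integer(factor(truth)))))
  expect_gte(agree, 0.95)
  # duplicated genotype rows yield identical component vectors
  dup <- sim$genotypes[c(1, 1, 2, 3), ]
  rownames(dup) <- c("a", "b", "c", "d")
  p2 <- compute_pcs(dup, 2)
  expect_equal(p2["a", ], p2["b", ], tolerance = 1e-9)
  expect_error(compute_pcs(sim$genotypes[1:3, 1:5], 10), "rank|non-monomorphic")
})

test_that("gate and label cluster assignment pass through as documented", {
  pcs <- matrix(c(-2, -2, 2, 2, 0, 0, 0.5, -0.5), 4, 2,
                dimnames = list(paste0("s", 1:4), c("PC1", "PC2")))
  g <- assign_cluster(pcs, "gate", list(xlim = c(-3, 0), ylim = c(-1, 1)))
  expect_equal(unname(g), c("C1", "C1", "C0", "C0"))
  l <- assign_cluster(pcs, "labels", list(labels = c("x", "y", "x", "y")))
  expect_equal(unname(l), c("x", "y", "x", "y"))
  expect_error(assign_cluster(pcs, "gate", list()), "xlim")
})

test_that("cluster carrier test composes labels with the Z test", {
  samples <- data.frame(
    sample_id = sprintf("S%04d", 1:1500),
    status = c(rep("case", 800), rep("control", 700)),
    stringsAsFactors = FALSE)
  labels <- setNames(c(rep("C1", 358), rep("C0", 442),
                       rep("C1", 337), rep("C0", 363)), samples$sample_id)
  carriers <- samples$sample_id[c(1:8, 400)]  # 8 cluster cases + 1 outside
  r <- cluster_carrier_test(carriers, labels, samples, "C1")
  expect_equal(r$k1, 8); expect_equal(r$n1, 358)
  expect_equal(r$k2, 0); expect_equal(r$n2, 337)
  expect_equal(round(r$z, 2), 2.76)
})
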