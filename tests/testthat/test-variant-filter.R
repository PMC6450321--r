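test_that("consequence terms map to the expected impact classes", {
  expect_equal(classify_impact("stop_gained"), "HIGH")
  expect_equal(classify_impact("missense_variant"), "MODERATE")
  expect_equal(classify_impact("synonymous_variant"), "LOW")
  expect_equal(classify_impact(c("frameshift_variant", "inframe_deletion")),
               c("HIGH", "MODERATE"))
  expect_warning(out <- classify_impact("weird_term"), "weird_term")
  expect_equal(out, "MODIFIER")
  # TSV override replaces the default table
  path <- tempfile()
  writeLines("missense_variant\tHIGH", path)
  expect_equal(classify_impact("missense_variant", table = path), "HIGH")
})

test_that("carrier counting distinguishes carriers, alleles, and missing calls", {
  samples <- toy_samples(3, 2)
  geno <- matrix(c(2L, 0L, NA, 0L, 0L,    # one homozygous case, one missing
                   NA, NA, NA, NA, NA),   # fully missing site
                 nrow = 5,
                 dimnames = list(samples$sample_id, c("1:100:A:T", "1:200:A:T")))
  cc <- count_carriers(geno, samples)
  v1 <- cc[cc$variant_key == "1:100:A:T", ]
  expect_equal(v1$n_case_carriers, 1)
  expect_equal(v1$case_alt_alleles, 2)
  expect_equal(v1$n_case_called, 2)  # the missing case is not in the denominator
  expect_equal(v1$n_control_called, 2)
  v2 <- cc[cc$variant_key == "1:200:A:T", ]
  expect_true(v2$all_missing)
  expect_equal(v2$n_case_carriers + v2$n_control_carriers, 0)
  expect_error(count_carriers(geno[1:4, ], samples), "match")
})

test_that("candidate-gene scheme applies the boundary thresholds exactly", {
  ann <- data.frame(
    variant_key = c("1:1:A:T", "1:2:A:T", "1:3:A:T", "1:4:A:T"),
    gene = c("NOTCH3", "NOTCH3", "OTHER", "NOTCH3"),
    consequence = "missense_variant",
    impact = c("MODERATE", "MODERATE", "MODERATE", "LOW"),
    stringsAsFactors = FALSE)
  counts <- data.frame(
    variant_key = ann$variant_key,
    n_case_carriers = c(4, 4, 10, 10),
    n_control_carriers = c(0, 1, 0, 0),
    stringsAsFactors = FALSE)
  sch <- filter_scheme("candidate_gene", gene_list = "NOTCH3")
  out <- apply_scheme(counts, ann, sch)
  # exactly 4 case carriers and 0 controls passes; one control carrier,
  # an off-list gene, or a LOW impact each fails
  expect_equal(out$variant_key, "1:1:A:T")
  dropped <- attr(out, "dropped")
  expect_equal(dropped$reason[dropped$variant_key == "1:2:A:T"],
               "control carriers present")
  expect_equal(dropped$reason[dropped$variant_key == "1:3:A:T"],
               "gene not in candidate list")
  expect_equal(dropped$reason[dropped$variant_key == "1:4:A:T"],
               "impact class not eligible")
})

test_that("multi-variant gene grouping keeps only genes with enough passing variants", {
  # 6-variant toy table checked exhaustively: GOOD has three passing
  # variants (5,0), (5,0), (6,0); BAD only two
  ann <- data.frame(
    variant_key = sprintf("1:%d:A:T", 1:6),
    gene = c("GOOD", "GOOD", "GOOD", "BAD", "BAD", "BAD"),
    consequence = "missense_variant", impact = "MODERATE",
    stringsAsFactors = FALSE)
  counts <- data.frame(
    variant_key = ann$variant_key,
    n_case_carriers = c(5, 5, 6, 5, 7, 4),
    n_control_carriers = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  out <- apply_scheme(counts, ann, filter_scheme("multi_variant_gene"))
  expect_setequal(out$variant_key, sprintf("1:%d:A:T", 1:3))
  expect_true(all(out$gene == "GOOD"))
  # with the BAD gene's third variant at the threshold, both genes pass
  counts$n_case_carriers[6] <- 5
  out2 <- apply_scheme(counts, ann, filter_scheme("multi_variant_gene"))
  expect_setequal(unique(out2$gene), c("GOOD", "BAD"))
})

test_that("filtering equals the brute-force oracle on random toy cohorts", {
  for (seed in c(11, 22, 33)) {
    toy <- random_counts_annotations(100, 50, 50, seed)
    cases <- list(
      list(sch = filter_scheme("candidate_gene",
                               gene_list = c("G01", "G02", "G03", "G04")),
           args = list(impacts = c("HIGH", "MODERATE"), min_case = 4,
                       gene_list = c("G01", "G02", "G03", "G04"))),
      list(sch = filter_scheme("genomewide_moderate_high"),
           args = list(impacts = c("HIGH", "MODERATE"), min_case = 10)),
      list(sch = filter_scheme("multi_variant_gene"),
           args = list(impacts = c("HIGH", "MODERATE"), min_case = 5,
                       min_distinct = 3)),
      list(sch = filter_scheme("genomewide_high"),
           args = list(impacts = "HIGH", min_case = 7)),
      list(sch = filter_scheme("genomewide_high", max_pop_af = 0.01),
           args = list(impacts = "HIGH", min_case = 7, max_pop_af = 0.01))
    )
    for (cs in cases) {
      got <- sort(apply_scheme(toy$counts, toy$annotations, cs$sch)$variant_key)
      want <- do.call(oracle_filter,
                      c(list(toy$counts, toy$annotations), cs$args))
      expect_identical(got, want, label = paste("seed", seed, cs$sch$name))
    }
  }
})

test_that("tightening a scheme never enlarges the retained set", {
  toy <- random_counts_annotations(100, 50, 50, 7)
  base <- apply_scheme(toy$counts, toy$annotations,
                       filter_scheme("genomewide_moderate_high",
                                     min_case_carriers = 4))$variant_key
  for (mc in c(6, 8, 10, 12)) {
    tighter <- apply_scheme(toy$counts, toy$annotations,
                            filter_scheme("genomewide_moderate_high",
                                          min_case_carriers = mc))$variant_key
    expect_true(all(tighter %in% base))
    base <- tighter
  }
  # shrinking the impact set also never enlarges the result
  wide <- apply_scheme(toy$counts, toy$annotations,
                       filter_scheme("genomewide_moderate_high",
                                     min_case_carriers = 5))$variant_key
  narrow <- apply_scheme(toy$counts, toy$annotations,
                         filter_scheme("genomewide_moderate_high",
                                       impacts = "HIGH",
                                       min_case_carriers = 5))$variant_key
  expect_true(all(narrow %in% wide))
})

test_that("noise-free simulations recover exactly the planted case-only variants", {
  sim <- simulate_cohort(simulation_config(
    n_cases = 60, n_controls = 60, n_background_snps = 150,
    planted = list(
      planted_variant("NOTCH3", "MODERATE", case_carriers = 10),  # passes
      planted_variant("PSEN1", "HIGH", case_carriers = 12),       # passes
      planted_variant("SORL1", "MODERATE", case_carriers = 9),    # below 10
      planted_variant("ABCA7", "HIGH", case_carriers = 11,
                      control_carriers = 1)                       # control carrier
    ), seed = 202))
  cc <- count_carriers(sim$genotypes, sim$samples)
  out <- apply_scheme(cc, sim$annotations,
                      filter_scheme("genomewide_moderate_high"))
  pl <- sim$truth$planted
  want <- pl$variant_key[pl$case_carriers >= 10 & pl$control_carriers == 0]
  expect_setequal(out$variant_key, want)
})

test_that("non-rare flags are advisory and threshold-driven", {
  ann <- data.frame(
    variant_key = c("a", "b", "c"), gene = "G",
    consequence = "missense_variant", impact = "MODERATE",
    af_nfe = c(0.024, 0.0005, NA),
    af_afr = c(0.091, 0.0001, NA),
    stringsAsFactors = FALSE)
  fl <- flag_nonrare(ann, af_threshold = 0.01)
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(fl$flag_population[1], "afr")  # the maximal population AF
  expect_false(any(flag_nonrare(ann, af_threshold = 1)$flagged))
})
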