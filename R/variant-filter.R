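# Impact classification, carrier counting, and the case-only filtering
# schemes that produce candidate variant lists. "Observed in N participants"
# counts carrier individuals (dosage >= 1), not alleles.

#' Default consequence-to-impact mapping
#'
#' Sequence-Ontology consequence terms mapped to the four functional impact
#' classes used by common annotation tools. Truncating and splice-disrupting
#' consequences are HIGH; protein-altering substitutions and in-frame indels
#' are MODERATE; synonymous changes are LOW; everything else is MODIFIER.
#'
#' @return A named character vector (term -> impact class).
#' @export
default_impact_table <- function() {
  c(
    stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
    frameshift_variant = "HIGH", splice_acceptor_variant = "HIGH",
    splice_donor_variant = "HIGH",
    missense_variant = "MODERATE", inframe_insertion = "MODERATE",
    inframe_deletion = "MODERATE", protein_altering_variant = "MODERATE",
    synonymous_variant = "LOW"
  )
}

#' Classify consequence terms into impact classes
#'
#' Maps Sequence-Ontology consequence terms to
#' HIGH/MODERATE/LOW/MODIFIER using [default_impact_table()] or a
#' user-supplied override (two-column TSV `consequence<TAB>impact`, since
#' annotation conventions differ between tools). Unrecognized terms map to
#' MODIFIER with a warning.
#'
#' @param consequence Character vector of consequence terms.
#' @param table Named character vector mapping terms to impact classes, or a
#'   path to a two-column TSV override.
#' @return Character vector of impact classes.
#' @export
#' @examples
#' classify_impact(c("stop_gained", "missense_variant"))
classify_impact <- function(consequence, table = default_impact_table()) {
  if (is.character(table) && length(table) == 1L && file.exists(table)) {
    df <- read.delim(table, header = FALSE, stringsAsFactors = FALSE)
    table <- stats::setNames(df[[2L]], df[[1L]])
  }
  if (any(!table %in% IMPACT_LEVELS)) {
    stop("impact table values must be HIGH/MODERATE/LOW/MODIFIER")
  }
  out <- unname(table[consequence])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("unrecognized consequence term(s) mapped to MODIFIER: %s",
                    paste(unique(consequence[unknown]), collapse = ", ")))
    out[unknown] <- "MODIFIER"
  }
  out
}

#' Tally case and control carriers per variant
#'
#' A carrier is a sample with at least one ALT allele (dosage >= 1).
#' Missing genotypes are excluded from the called denominators; a sample
#' with a missing call is neither a carrier nor evidence of absence.
#'
#' @param genotypes Dosage matrix (samples x variants, `NA` = missing).
#' @param samples Phenotype data.frame with `sample_id` and `status`
#'   (`"case"`/`"control"`) covering every row of `genotypes`.
#' @return A data.frame with one row per variant: `variant_key`,
#'   `n_case_carriers`, `n_control_carriers`, `case_alt_alleles`,
#'   `control_alt_alleles`, `n_case_called`, `n_control_called`, and
#'   `all_missing` flagging sites with no called genotype.
#' @export
count_carriers <- function(genotypes, samples) {
  ids <- rownames(genotypes)
  if (is.null(ids) || !setequal(ids, samples$sample_id) ||
      anyDuplicated(samples$sample_id)) {
    stop("sample ids of genotype matrix and phenotype table do not match")
  }
  status <- samples$status[match(ids, samples$sample_id)]
  is_case <- status == "case"
  tally <- function(g) {
    called <- !is.na(g)
    carrier <- called & g >= 1L
    c(sum(carrier & is_case), sum(carrier & !is_case),
      sum(g[called & is_case]), sum(g[called & !is_case]),
      sum(called & is_case), sum(called & !is_case))
  }
  m <- vapply(seq_len(ncol(genotypes)), function(j) tally(genotypes[, j]),
              numeric(6))
  out <- data.frame(
    variant_key = colnames(genotypes),
    n_case_carriers = m[1, ], n_control_carriers = m[2, ],
    case_alt_alleles = m[3, ], control_alt_alleles = m[4, ],
    n_case_called = m[5, ], n_control_called = m[6, ],
    stringsAsFactors = FALSE
  )
  out$all_missing <- out$n_case_called + out$n_control_called == 0
  out
}

#' Define a case-only filtering scheme
#'
#' The four named presets correspond to the discovery strategies of a
#' case-only rare-variant screen in a dementia cohort:
#' \describe{
#'   \item{candidate_gene}{HIGH or MODERATE impact variants in a prior
#'     candidate gene list, carried by >= 4 cases and no controls.}
#'   \item{genomewide_moderate_high}{HIGH or MODERATE impact, >= 10 case
#'     carriers, no controls, any gene.}
#'   \item{multi_variant_gene}{genes harboring >= 3 distinct HIGH/MODERATE
#'     variants, each carried by >= 5 cases and no controls.}
#'   \item{genomewide_high}{HIGH impact only, >= 7 case carriers, no
#'     controls.}
#' }
#' Every preset parameter can be overridden.
#'
#' @param name One of the four preset names.
#' @param impacts Impact classes a variant must have (subset of
#'   HIGH/MODERATE).
#' @param min_case_carriers Minimum number of case carriers.
#' @param max_control_carriers Maximum number of called control carriers
#'   (default 0: "absent in controls").
#' @param gene_list Optional character vector of gene symbols restricting
#'   candidates (required for `candidate_gene`).
#' @param min_distinct_variants_per_gene For `multi_variant_gene`: minimum
#'   number of passing variants a gene must contain.
#' @param max_pop_af Optional cutoff applied to every population AF column.
#' @return An object of class `filter_scheme`.
#' @export
filter_scheme <- function(name = c("candidate_gene", "genomewide_moderate_high",
                                   "multi_variant_gene", "genomewide_high"),
                          impacts = NULL, min_case_carriers = NULL,
                          max_control_carriers = 0L, gene_list = NULL,
                          min_distinct_variants_per_gene = NULL,
                          max_pop_af = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    candidate_gene = list(impacts = c("HIGH", "MODERATE"), min_case = 4L, min_distinct = NULL),
    genomewide_moderate_high = list(impacts = c("HIGH", "MODERATE"), min_case = 10L, min_distinct = NULL),
    multi_variant_gene = list(impacts = c("HIGH", "MODERATE"), min_case = 5L, min_distinct = 3L),
    genomewide_high = list(impacts = "HIGH", min_case = 7L, min_distinct = NULL)
  )
  scheme <- list(
    name = name,
    impacts = if (is.null(impacts)) preset$impacts else impacts,
    min_case_carriers = if (is.null(min_case_carriers)) preset$min_case else min_case_carriers,
    max_control_carriers = max_control_carriers,
    gene_list = gene_list,
    min_distinct_variants_per_gene =
      if (is.null(min_distinct_variants_per_gene)) preset$min_distinct
      else min_distinct_variants_per_gene,
    max_pop_af = max_pop_af
  )
  if (!all(scheme$impacts %in% c("HIGH", "MODERATE"))) {
    stop("scheme impacts must be a subset of HIGH, MODERATE")
  }
  if (scheme$min_case_carriers < 0 || scheme$max_control_carriers < 0) {
    stop("carrier thresholds must be non-negative")
  }
  if (name == "candidate_gene" && is.null(gene_list)) {
    stop("candidate_gene scheme requires a gene_list")
  }
  structure(scheme, class = "filter_scheme")
}

#' @export
print.filter_scheme <- function(x, ...) {
  cat(sprintf("Case-only filter scheme '%s'\n", x$name))
  cat(sprintf("  impacts: %s\n", paste(x$impacts, collapse = ", ")))
  cat(sprintf("  case carriers >= %d, control carriers <= %d\n",
              x$min_case_carriers, x$max_control_carriers))
  if (!is.null(x$gene_list)) cat(sprintf("  gene list: %d genes\n", length(x$gene_list)))
  if (!is.null(x$min_distinct_variants_per_gene)) {
    cat(sprintf("  genes need >= %d distinct passing variants\n",
                x$min_distinct_variants_per_gene))
  }
  if (!is.null(x$max_pop_af)) cat(sprintf("  population AF <= %g\n", x$max_pop_af))
  invisible(x)
}

#' Apply a case-only filtering scheme
#'
#' A variant is retained when its impact class is in `scheme$impacts`, it
#' has at least `min_case_carriers` case carriers and at most
#' `max_control_carriers` called control carriers, its gene is in
#' `gene_list` (when given), and every population AF is at or below
#' `max_pop_af` (when given). Under `multi_variant_gene` semantics, passing
#' variants are additionally grouped by gene and only genes with at least
#' `min_distinct_variants_per_gene` passing variants are kept.
#'
#' @param counts Carrier-count table from [count_carriers()].
#' @param annotations Annotation data.frame; every candidate variant that
#'   survives the carrier thresholds must be annotated.
#' @param scheme A [filter_scheme()].
#' @return A data.frame of retained variants (`variant_key`, `gene`,
#'   `impact`, carrier counts, AF columns) with attribute `"dropped"`: a
#'   data.frame of excluded candidates and the first rule each one failed.
#' @export
apply_scheme <- function(counts, annotations, scheme) {
  stopifnot(inherits(scheme, "filter_scheme"))
  df <- merge(counts, annotations, by = "variant_key")
  af_cols <- grep("^af_", names(df), value = TRUE)
  reason <- rep(NA_character_, nrow(df))
  fail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  fail(!df$impact %in% scheme$impacts, "impact class not eligible")
  fail(df$n_case_carriers < scheme$min_case_carriers, "too few case carriers")
  fail(df$n_control_carriers > scheme$max_control_carriers, "control carriers present")
  if (!is.null(scheme$gene_list)) {
    fail(!df$gene %in% scheme$gene_list, "gene not in candidate list")
  }
  if (!is.null(scheme$max_pop_af) && length(af_cols)) {
    over <- Reduce(`|`, lapply(af_cols, function(cl) {
      !is.na(df[[cl]]) & df[[cl]] > scheme$max_pop_af
    }))
    fail(over, "population AF above cutoff")
  }
  pass <- is.na(reason)
  if (!is.null(scheme$min_distinct_variants_per_gene)) {
    per_gene <- table(df$gene[pass])
    ok_genes <- names(per_gene)[per_gene >= scheme$min_distinct_variants_per_gene]
    fail(pass & !df$gene %in% ok_genes, "too few distinct passing variants in gene")
    pass <- is.na(reason)
  }
  keep_cols <- c("variant_key", "gene", "consequence", "impact",
                 "n_case_carriers", "n_control_carriers",
                 "n_case_called", "n_control_called", af_cols)
  keep_cols <- intersect(keep_cols, names(df))
  retained <- df[pass, keep_cols, drop = FALSE]
  retained <- retained[order(retained$gene, retained$variant_key), , drop = FALSE]
  rownames(retained) <- NULL
  dropped <- data.frame(variant_key = df$variant_key[!pass],
                        gene = df$gene[!pass],
                        reason = reason[!pass], stringsAsFactors = FALSE)
  attr(retained, "dropped") <- dropped
  attr(retained, "scheme") <- scheme$name
  retained
}

#' Flag variants that are not rare in some reference population
#'
#' Advisory (not a hard filter): a case-only variant that is common in a
#' reference population is unlikely to be highly penetrant, so it is flagged
#' for review rather than removed.
#'
#' @param annotations Annotation data.frame with `af_*` columns.
#' @param af_threshold Frequency above which a variant is flagged
#'   (default 0.01).
#' @return A data.frame `variant_key`, `flagged`, `max_pop_af`,
#'   `flag_population` (population of the maximal AF, `NA` when unflagged).
#' @export
flag_nonrare <- function(annotations, af_threshold = 0.01) {
  af_cols <- grep("^af_", names(annotations), value = TRUE)
  if (!length(af_cols)) stop("annotations carry no population AF (af_*) columns")
  af <- as.matrix(annotations[, af_cols, drop = FALSE])
  max_af <- apply(af, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  which_pop <- af_cols[apply(af, 1, function(x) {
    if (all(is.na(x))) NA_integer_ else which.max(x)
  })]
  flagged <- !is.na(max_af) & max_af > af_threshold
  data.frame(
    variant_key = annotations$variant_key,
    flagged = flagged,
    max_pop_af = max_af,
    flag_population = ifelse(flagged, sub("^af_", "", which_pop), NA_character_),
    stringsAsFactors = FALSE
  )
}
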