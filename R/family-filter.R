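# Pedigree variant filters for affected-relative sequencing designs:
# sharing among genotyped affected members, population frequency,
# predicted impact, and gene relevance.

#' Configure the family variant filters
#'
#' @param max_pop_af Maximum allele frequency allowed in every listed
#'   reference population.
#' @param impacts Qualifying impact classes (subset of HIGH/MODERATE); this
#'   operationalizes the pathogenicity filter by predicted consequence
#'   class. An external score column can be supplied via `score_column`
#'   and `score_min`.
#' @param relevance_genes Optional character vector restricting variants to
#'   disease-relevant genes. Pass `NULL` to skip the filter; an explicitly
#'   empty vector is rejected as almost certainly a mistake.
#' @param require_all_affected When `TRUE` (default), a missing genotype in
#'   an affected member blocks sharing (conservative); when `FALSE`,
#'   members with missing calls are ignored at that site.
#' @param score_column,score_min Optional annotation column holding an
#'   external pathogenicity score and the minimum value to retain.
#' @return A list of class `family_filter_config`.
#' @export
family_filter_config <- function(max_pop_af = 0.001,
                                 impacts = c("HIGH", "MODERATE"),
                                 relevance_genes = NULL,
                                 require_all_affected = TRUE,
                                 score_column = NULL, score_min = NULL) {
  stopifnot(max_pop_af >= 0, max_pop_af <= 1,
            all(impacts %in% c("HIGH", "MODERATE")))
  if (!is.null(relevance_genes) && !length(relevance_genes)) {
    stop("relevance_genes is empty; pass NULL to skip the relevance filter")
  }
  structure(list(max_pop_af = max_pop_af, impacts = impacts,
                 relevance_genes = relevance_genes,
                 require_all_affected = require_all_affected,
                 score_column = score_column, score_min = score_min),
            class = "family_filter_config")
}

#' Variants shared by all genotyped affected members
#'
#' Returns the variant keys at which every genotyped affected member of the
#' pedigree carries at least one ALT allele. Ungenotyped affected members
#' are ignored. With `require_all_affected` (default), a missing genotype
#' in any genotyped affected member blocks the variant; otherwise members
#' missing at a site are dropped from the requirement for that site (at
#' least one called carrier is still required).
#'
#' @param pedigree Single-family pedigree data.frame (see [read_ped()]).
#' @param genotypes Dosage matrix with the genotyped members among its
#'   rows.
#' @param require_all_affected Missing-call policy, see above.
#' @return Character vector of shared variant keys.
#' @export
shared_in_affected <- function(pedigree, genotypes,
                               require_all_affected = TRUE) {
  aff <- pedigree$id[pedigree$affected == "yes" & pedigree$genotyped]
  aff <- intersect(aff, rownames(genotypes))
  if (length(aff) < 2L) {
    stop(sprintf("need >= 2 genotyped affected members, found %d", length(aff)))
  }
  g <- genotypes[aff, , drop = FALSE]
  carrier <- !is.na(g) & g >= 1L
  shared <- if (require_all_affected) {
    colSums(carrier) == length(aff) & colSums(is.na(g)) == 0L
  } else {
    called <- colSums(!is.na(g))
    colSums(carrier) == called & called >= 1L
  }
  colnames(g)[shared]
}

#' Apply frequency, impact, and relevance filters to shared variants
#'
#' Sequential filters on the affected-shared variant list: every listed
#' population AF at or below `max_pop_af`; impact class among
#' `config$impacts` (optionally an external pathogenicity score threshold);
#' gene in `relevance_genes` when provided. The filters are independent
#' predicates, so the retained set does not depend on their order; the
#' per-step removal counts refer to the order stated.
#'
#' @param shared_keys Variant keys from [shared_in_affected()].
#' @param annotations Annotation data.frame covering all shared variants.
#' @param config A [family_filter_config()].
#' @return A data.frame of retained variants with attributes `"dropped"`
#'   (variant, first failed rule) and `"step_counts"` (named removal
#'   counts).
#' @export
apply_family_filters <- function(shared_keys, annotations, config) {
  stopifnot(inherits(config, "family_filter_config"))
  ann <- annotations[match(shared_keys, annotations$variant_key), , drop = FALSE]
  if (any(is.na(ann$variant_key))) {
    stop(sprintf("no annotation for: %s",
                 paste(shared_keys[is.na(ann$variant_key)], collapse = ", ")))
  }
  af_cols <- grep("^af_", names(ann), value = TRUE)
  reason <- rep(NA_character_, nrow(ann))
  steps <- c(frequency = 0L, impact = 0L, relevance = 0L)

  if (length(af_cols)) {
    over <- Reduce(`|`, lapply(af_cols, function(cl) {
      !is.na(ann[[cl]]) & ann[[cl]] > config$max_pop_af
    }))
    steps["frequency"] <- sum(over & is.na(reason))
    reason[is.na(reason) & over] <- "population AF above cutoff"
  }
  bad_imp <- !ann$impact %in% config$impacts
  if (!is.null(config$score_column)) {
    sc <- ann[[config$score_column]]
    if (is.null(sc)) stop(sprintf("score column %s absent", config$score_column))
    bad_imp <- bad_imp | (!is.na(sc) & sc < config$score_min)
  }
  steps["impact"] <- sum(bad_imp & is.na(reason))
  reason[is.na(reason) & bad_imp] <- "impact/pathogenicity not qualifying"
  if (!is.null(config$relevance_genes)) {
    bad_gene <- !ann$gene %in% config$relevance_genes
    steps["relevance"] <- sum(bad_gene & is.na(reason))
    reason[is.na(reason) & bad_gene] <- "gene not disease-relevant"
  }

  keep <- is.na(reason)
  retained <- ann[keep, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "dropped") <- data.frame(
    variant_key = ann$variant_key[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  attr(retained, "step_counts") <- steps
  retained
}
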