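# Shared domain containers and readers/writers for the standard formats the
# pipeline touches. Variants live in a data.frame (chrom, pos, id, ref, alt,
# variant_key); genotypes in an integer matrix (samples x variants, entries
# 0/1/2 counting ALT alleles, NA = missing) whose dimnames carry sample ids
# and variant keys.

#' Canonical variant key
#'
#' Variants are identified throughout the pipeline by the string
#' `"chrom:pos:ref:alt"` with 1-based VCF coordinates.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position (bp).
#' @param ref Reference allele.
#' @param alt Single alternate allele.
#' @return Character vector of keys.
#' @export
#' @examples
#' variant_key("19", 15191610, "G", "A")
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

new_variant_table <- function(chrom, pos, id, ref, alt) {
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("variant positions must be >= 1")
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  data.frame(
    chrom = as.character(chrom), pos = pos, id = as.character(id),
    ref = as.character(ref), alt = as.character(alt),
    variant_key = variant_key(chrom, pos, ref, alt),
    stringsAsFactors = FALSE
  )
}

# Decode one GT string into an ALT-allele index pair, or NULL for missing.
# Half-calls ("./1") are treated as missing: a missing allele call gives no
# evidence of carrier status, so the conservative choice drops the genotype.
gt_alleles <- function(gt) {
  if (is.na(gt)) return(NULL)  # vcfR renders ./. as NA
  gt <- sub(":.*", "", gt)
  a <- strsplit(gt, "[/|]")[[1]]
  if (length(a) == 1L) a <- c(a, a)  # haploid call treated as homozygous
  if (length(a) != 2L || any(!grepl("^([0-9]+|\\.)$", a))) {
    return(NA)  # malformed, caller raises
  }
  if (any(a == ".")) return(NULL)
  as.integer(a)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (optionally gzip-compressed) with a `GT` FORMAT
#' field into a variant table and a dosage matrix. Multiallelic records are
#' decomposed into one biallelic record per ALT allele; the dosage of each
#' decomposed record counts that ALT allele only, so per-sample dosages over
#' the decomposed records sum to the original ALT-allele count. Missing
#' (`./.`) and half-called genotypes become `NA`; phase separators (`|`) are
#' ignored for dosage.
#'
#' @param path Path to the VCF file.
#' @param region Optional `"chrom:start-end"` string restricting the records
#'   returned (1-based, inclusive).
#' @return A list with `variants` (data.frame: chrom, pos, id, ref, alt,
#'   variant_key) and `genotypes` (integer matrix samples x variants; rows
#'   named by sample id, columns by variant key).
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF has no genotype columns")
  }
  fmt <- gt_raw[, 1L]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)GT(:|$)", fmt))[1L]
    stop(sprintf("record %d: FORMAT lacks GT", bad))
  }
  samples <- colnames(gt_raw)[-1L]
  n_sam <- length(samples)

  chrom_out <- character(0); pos_out <- integer(0); id_out <- character(0)
  ref_out <- character(0); alt_out <- character(0)
  dos_cols <- list()

  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    # decode every sample once per record
    pairs <- vector("list", n_sam)
    for (s in seq_len(n_sam)) {
      al <- gt_alleles(gt_raw[r, s + 1L])
      if (length(al) == 1L && is.na(al[1L])) {
        stop(sprintf("record %d, sample %s: malformed GT '%s'",
                     r, samples[s], gt_raw[r, s + 1L]))
      }
      pairs[[s]] <- al
    }
    for (a in seq_along(alts)) {
      dose <- vapply(pairs, function(p) {
        if (is.null(p)) return(NA_integer_)
        sum(p == a)
      }, integer(1))
      chrom_out <- c(chrom_out, fix[r, "CHROM"])
      pos_out <- c(pos_out, as.integer(fix[r, "POS"]))
      id_out <- c(id_out, ifelse(is.na(fix[r, "ID"]), ".", fix[r, "ID"]))
      ref_out <- c(ref_out, fix[r, "REF"])
      alt_out <- c(alt_out, alts[a])
      dos_cols[[length(dos_cols) + 1L]] <- dose
    }
  }

  variants <- new_variant_table(chrom_out, pos_out, id_out, ref_out, alt_out)
  geno <- matrix(unlist(dos_cols), nrow = n_sam,
                 dimnames = list(samples, variants$variant_key))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must be 'chrom:start-end'")
    keep <- variants$chrom == m[2L] &
      variants$pos >= as.integer(m[3L]) & variants$pos <= as.integer(m[4L])
    variants <- variants[keep, , drop = FALSE]
    geno <- geno[, keep, drop = FALSE]
  }
  list(variants = variants, genotypes = geno)
}

#' Write a cohort back to a VCF 4.2 file
#'
#' Emits a minimal deterministic plain-text VCF with a `GT` FORMAT field.
#' Dosage 0/1/2 is coded `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#'
#' @param variants Variant table as returned by [read_vcf()].
#' @param genotypes Dosage matrix (samples x variants).
#' @param path Output path.
#' @param header_extra Optional character vector of extra `##` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, genotypes, path, header_extra = NULL) {
  stopifnot(nrow(variants) == ncol(genotypes))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=caseonly-%s", as.character(utils::packageVersion("caseonly"))),
    header_extra,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(variants))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a variant annotation table
#'
#' Two dialects are supported. `"tsv"` expects a header row with columns
#' `variant_key`, `gene`, `consequence`, `impact` plus any number of
#' population allele-frequency columns named `af_<population>`. `"vcf_ann"`
#' parses a SnpEff-style `ANN=` INFO field from a VCF
#' (`Allele|Annotation|Impact|Gene|...`), producing one row per
#' (variant, gene) pair; population AF columns are taken from INFO keys
#' beginning `AF_`.
#'
#' @param path Path to the TSV or VCF file.
#' @param dialect `"tsv"` or `"vcf_ann"`.
#' @return A data.frame with columns `variant_key`, `gene`, `consequence`,
#'   `impact` and zero or more `af_*` columns (values in `[0, 1]`).
#' @export
read_annotations <- function(path, dialect = c("tsv", "vcf_ann")) {
  dialect <- match.arg(dialect)
  ann <- if (dialect == "tsv") read_annotations_tsv(path) else read_annotations_ann(path)
  bad <- !ann$impact %in% IMPACT_LEVELS
  if (any(bad)) {
    stop(sprintf("unknown impact class(es): %s",
                 paste(unique(ann$impact[bad]), collapse = ", ")))
  }
  af_cols <- grep("^af_", names(ann), value = TRUE)
  for (cl in af_cols) {
    if (any(!is.na(ann[[cl]]) & (ann[[cl]] < 0 | ann[[cl]] > 1))) {
      stop(sprintf("allele frequencies in column %s outside [0, 1]", cl))
    }
  }
  ann
}

read_annotations_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("variant_key", "gene", "consequence", "impact")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("annotation TSV missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(df)
  df
}

read_annotations_ann <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  out <- list()
  for (r in seq_len(nrow(fix))) {
    info <- fix[r, "INFO"]
    kv <- strsplit(info, ";", fixed = TRUE)[[1]]
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=?", "", kv)
    ann_str <- vals[keys == "ANN"]
    if (!length(ann_str)) next
    afs <- vals[grepl("^AF_", keys)]
    af_names <- tolower(keys[grepl("^AF_", keys)])
    for (entry in strsplit(ann_str, ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) < 4L) stop(sprintf("record %d: malformed ANN entry '%s'", r, entry))
      row <- data.frame(
        variant_key = variant_key(fix[r, "CHROM"], as.integer(fix[r, "POS"]),
                                  fix[r, "REF"], f[1L]),
        gene = f[4L], consequence = f[2L], impact = f[3L],
        stringsAsFactors = FALSE
      )
      for (i in seq_along(afs)) row[[af_names[i]]] <- as.numeric(afs[i])
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    return(data.frame(variant_key = character(0), gene = character(0),
                      consequence = character(0), impact = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a sample phenotype/covariate table
#'
#' Expects a TSV with header columns `sample_id`, `status`, `sex`, `age`,
#' `center`, principal-component columns `pc1`, `pc2`, ... and an optional
#' `cluster` column. Case/control status may be coded either as the strings
#' `case`/`control` or PLINK-style `2`/`1` integers.
#'
#' @param path Path to the TSV file.
#' @param status_coding `"labels"` for case/control strings, `"plink"` for
#'   2 = case, 1 = control.
#' @return A data.frame with `status` normalized to `"case"`/`"control"`.
#' @export
read_phenotypes <- function(path, status_coding = c("labels", "plink")) {
  status_coding <- match.arg(status_coding)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("phenotype file missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype file")
  df$status <- if (status_coding == "plink") {
    c(`1` = "control", `2` = "case")[as.character(df$status)]
  } else as.character(df$status)
  if (any(is.na(df$status)) || !all(df$status %in% c("case", "control"))) {
    stop("status must be case/control (or 2/1 with status_coding = 'plink')")
  }
  pc_cols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  for (cl in pc_cols) {
    if (any(!is.finite(df[[cl]]))) stop(sprintf("non-finite values in %s", cl))
  }
  df
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop(sprintf("GMT line with fewer than 3 fields: '%s'", ln))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("empty gene set '%s'", f[1L]))
    if (f[1L] %in% names(sets)) stop(sprintf("duplicate gene set name '%s'", f[1L]))
    sets[[f[1L]]] <- genes
  }
  sets
}

#' Read pedigrees from a PED file
#'
#' Standard whitespace-delimited 6-column PED (family, individual, father,
#' mother, sex, affection) with an optional 7th column flagging whether the
#' individual was genotyped (1/0). Parent id `"0"` means unknown. Affection
#' uses 2 = affected, 1 = unaffected, 0/-9 = unknown.
#'
#' @param path Path to the PED file.
#' @return A data.frame with columns `family_id`, `id`, `father`, `mother`
#'   (`NA` when unknown), `sex`, `affected` (`"yes"`/`"no"`/`"unknown"`),
#'   `genotyped` (logical).
#' @export
read_ped <- function(path) {
  nf <- utils::count.fields(path)
  if (any(nf < 6L)) stop("PED file must have at least 6 columns")
  df <- utils::read.table(path, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("family_id", "id", "father", "mother", "sex", "aff")
  if (ncol(df) >= 7L) names(df)[7] <- "genotyped" else df$genotyped <- 1L
  ped <- data.frame(
    family_id = as.character(df$family_id), id = as.character(df$id),
    father = ifelse(df$father == "0", NA_character_, as.character(df$father)),
    mother = ifelse(df$mother == "0", NA_character_, as.character(df$mother)),
    sex = as.character(df$sex),
    affected = c(`2` = "yes", `1` = "no", `0` = "unknown",
                 `-9` = "unknown")[as.character(df$aff)],
    genotyped = df$genotyped != 0L,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(ped$family_id, ped$id))) {
    stop("duplicate individual ids within a family")
  }
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    for (p in c(sub$father, sub$mother)) {
      if (!is.na(p) && !p %in% sub$id) {
        stop(sprintf("family %s: parent %s not present", fam, p))
      }
    }
    check_pedigree_acyclic(sub)
  }
  ped
}

# Topological order of a single-family pedigree; errors on a loop.
pedigree_order <- function(ped) {
  remaining <- ped$id
  placed <- character(0)
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$father) || r$father %in% placed) &&
        (is.na(r$mother) || r$mother %in% placed)
    }, logical(1))
    if (!any(ready)) {
      stop(sprintf("pedigree loop involving: %s", paste(remaining, collapse = ", ")))
    }
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

check_pedigree_acyclic <- function(ped) invisible(pedigree_order(ped))
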