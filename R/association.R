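# Inferential statistics: two-proportion carrier-enrichment Z test,
# collapsed (CMC) rare-variant burden regression with a Firth fallback,
# hypergeometric gene-set over-representation with BH-FDR, and ancestry
# principal components with subcluster assignment.

#' Two-proportion Z test with pooled variance
#'
#' Compares carrier proportions between two groups using the pooled
#' proportion standard error with no continuity correction:
#' `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (k1 + k2) / (n1 + n2)`, and a two-sided normal p-value.
#'
#' @param k1,n1 Carriers and total in group 1.
#' @param k2,n2 Carriers and total in group 2.
#' @return A list of class `prop_test`: `k1`, `n1`, `k2`, `n2`, `p1`, `p2`,
#'   `z`, `p_two_sided`, `degenerate` (TRUE when the pooled proportion is 0
#'   or 1, leaving no variance; then `z = 0`).
#' @export
#' @examples
#' two_proportion_z(8, 358, 0, 337)
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  phat <- (k1 + k2) / (n1 + n2)
  degenerate <- phat %in% c(0, 1)
  z <- if (degenerate) 0 else {
    (p1 - p2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  }
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
                 z = z, p_two_sided = if (degenerate) 1 else 2 * pnorm(-abs(z)),
                 degenerate = degenerate),
            class = "prop_test")
}

#' @export
print.prop_test <- function(x, ...) {
  cat(sprintf("Two-proportion Z: %d/%d (%.1f%%) vs %d/%d (%.1f%%): Z = %.2f, P = %.3g%s\n",
              x$k1, x$n1, 100 * x$p1, x$k2, x$n2, 100 * x$p2, x$z,
              x$p_two_sided, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Collapse qualifying rare variants into per-sample burdens (CMC)
#'
#' Qualifying variants have impact in `impacts`, gene in `gene_set`, and
#' sample minor allele frequency at most `maf_max`. The default `"count"`
#' collapse sums minor-allele dosages over qualifying variants per sample;
#' `"indicator"` is the classical collapse to a 0/1 carrier flag. Missing
#' genotypes contribute zero.
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param annotations Annotation data.frame (`variant_key`, `gene`,
#'   `impact`).
#' @param gene_set Character vector of gene symbols defining the set.
#' @param impacts Qualifying impact classes.
#' @param maf_max Maximum sample MAF (default 0.01, the usual "rare"
#'   stratum).
#' @param mode `"count"` or `"indicator"`.
#' @return Named numeric vector of per-sample burdens with attribute
#'   `"qualifying"`: the qualifying variant keys.
#' @export
cmc_collapse <- function(genotypes, annotations, gene_set,
                         impacts = c("HIGH", "MODERATE"), maf_max = 0.01,
                         mode = c("count", "indicator")) {
  mode <- match.arg(mode)
  ann <- annotations[annotations$impact %in% impacts &
                       annotations$gene %in% gene_set, , drop = FALSE]
  keys <- intersect(unique(ann$variant_key), colnames(genotypes))
  if (length(keys)) {
    af <- colMeans(genotypes[, keys, drop = FALSE], na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    keys <- keys[!is.na(maf) & maf <= maf_max]
  }
  if (!length(keys)) {
    stop(sprintf(
      "no qualifying variants (impacts %s, %d genes, sample MAF <= %g)",
      paste(impacts, collapse = "/"), length(gene_set), maf_max))
  }
  sub <- genotypes[, keys, drop = FALSE]
  sub[is.na(sub)] <- 0L
  burden <- if (mode == "count") rowSums(sub) else as.numeric(rowSums(sub) > 0)
  attr(burden, "qualifying") <- keys
  attr(burden, "mode") <- mode
  burden
}

# Firth-penalized logistic regression by Newton iteration on the modified
# score U*_j = sum_i (y_i - mu_i + h_i (1/2 - mu_i)) x_ij, used when
# ordinary ML fails through separation.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  b <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    XtWX_inv <- solve(XtWX)
    # leverages of the weighted design
    h <- rowSums((X %*% XtWX_inv) * X) * w
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(XtWX_inv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(XtWX_inv))
  list(coef = b, se = se, n_iter = it)
}

#' Rare-variant burden logistic regression
#'
#' Fits case/control status on a per-sample burden with covariates for sex,
#' age, sequencing center, and ancestry principal components, by
#' maximum-likelihood logistic regression (IRLS). When the fit shows
#' complete or quasi-complete separation, a Firth-penalized fit is used
#' instead and flagged.
#'
#' @param burden Per-sample burden vector from [cmc_collapse()] (names =
#'   sample ids).
#' @param samples Phenotype data.frame with `sample_id`, `status`, and the
#'   requested covariate columns.
#' @param covariates Covariate columns to include (centers and other
#'   categoricals are one-hot encoded with the first level as reference;
#'   age enters linearly).
#' @param n_pcs Number of `pc*` columns to include (0 to omit).
#' @return A list of class `burden_result`: `beta` (log-odds per unit
#'   burden), `se`, `z`, `p`, cumulative qualifying-variant counts by
#'   status (`n_carrier_variants_cases`, `n_carrier_variants_controls`),
#'   `model` (description), `firth` (fallback flag).
#' @export
burden_logistic <- function(burden, samples,
                            covariates = c("sex", "age", "center"),
                            n_pcs = 2L) {
  ids <- names(burden)
  if (is.null(ids)) {
    if (length(burden) != nrow(samples)) stop("burden and samples do not align")
    ids <- samples$sample_id
  }
  df <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (any(is.na(df$sample_id))) stop("burden names missing from samples")
  if (length(unique(df$status)) < 2L) stop("both outcome classes must be present")
  if (all(burden == burden[1L])) stop("burden has no variation")

  y <- as.integer(df$status == "case")
  pc_cols <- if (n_pcs > 0L) paste0("pc", seq_len(n_pcs)) else character(0)
  pc_cols <- intersect(pc_cols, names(df))
  covariates <- intersect(covariates, names(df))
  mm_terms <- c("burden", covariates, pc_cols)
  mf <- data.frame(y = y, burden = as.numeric(burden))
  for (cv in c(covariates, pc_cols)) {
    col <- df[[cv]]
    # drop constant covariates (e.g. a single sequencing center)
    if (length(unique(col[!is.na(col)])) < 2L) {
      mm_terms <- setdiff(mm_terms, cv)
      next
    }
    mf[[cv]] <- if (is.character(col)) factor(col) else col
  }
  form <- stats::as.formula(paste("y ~", paste(mm_terms, collapse = " + ")))
  X <- stats::model.matrix(form, mf)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")

  fit <- suppressWarnings(glm(form, family = binomial(), data = mf,
                              control = list(epsilon = 1e-8, maxit = 50L)))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    ff <- firth_logistic(X, y)
    beta <- ff$coef[colnames(X) == "burden"]
    se <- ff$se[colnames(X) == "burden"]
  } else {
    beta <- coef(fit)[["burden"]]
    se <- sqrt(vcov(fit)["burden", "burden"])
  }
  z <- beta / se
  # cumulative qualifying minor alleles by status
  cum_case <- sum(burden[y == 1L])
  cum_ctrl <- sum(burden[y == 0L])
  structure(list(
    beta = unname(beta), se = unname(se), z = unname(z),
    p = 2 * pnorm(-abs(z)),
    n_carrier_variants_cases = cum_case,
    n_carrier_variants_controls = cum_ctrl,
    model = sprintf("status ~ burden + %s (logistic%s)",
                    paste(setdiff(mm_terms, "burden"), collapse = " + "),
                    if (separated) ", Firth penalized" else ""),
    firth = separated
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("Burden test: beta (SE) = %.3f (%.3f), P = %.3g%s\n",
              x$beta, x$se, x$p, if (x$firth) " [Firth]" else ""))
  cat(sprintf("  cumulative qualifying variants: %g cases vs %g controls\n",
              x$n_carrier_variants_cases, x$n_carrier_variants_controls))
  cat(sprintf("  model: %s\n", x$model))
  invisible(x)
}

#' Gene-set over-representation by the hypergeometric upper tail
#'
#' Tests whether a gene network is over-represented in each pathway gene
#' set: with a universe of `universe_size` genes of which `n_annotated`
#' belong to the pathway, drawing `|network|` genes and observing
#' `n_observed` pathway members, the one-tailed p-value is
#' `P(X >= n_observed)` for hypergeometric X. The expected count is
#' `|network| * n_annotated / universe_size` and fold enrichment is
#' observed/expected. P-values are BH-adjusted across pathways.
#'
#' @param network Character vector of network gene symbols.
#' @param pathways Named list of pathway gene sets (as from [read_gmt()]).
#' @param universe_size Number of genes in the annotation universe
#'   (default 20996, annotated human protein-coding genes).
#' @return A data.frame with one row per pathway: `pathway`, `n_annotated`,
#'   `n_observed`, `expected`, `fold`, `p_unadjusted`, `fdr`.
#' @export
fisher_enrichment <- function(network, pathways, universe_size = 20996) {
  network <- unique(network)
  k <- length(network)
  if (universe_size < k) stop("universe smaller than the network")
  rows <- lapply(names(pathways), function(nm) {
    genes <- unique(pathways[[nm]])
    m <- length(genes)
    obs <- length(intersect(network, genes))
    if (obs > min(m, k)) stop("observed overlap exceeds set sizes")
    expected <- k * m / universe_size
    data.frame(pathway = nm, n_annotated = m, n_observed = obs,
               expected = expected,
               fold = if (expected > 0) obs / expected else 0,
               p_unadjusted = phyper(obs - 1, m, universe_size - m, k,
                                     lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_unadjusted)
  out[order(out$p_unadjusted), , drop = FALSE]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `min over j >= rank(i) of p_(j) * m / j`, capped at
#' 1; ties handled stably.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Ancestry principal components of a dosage matrix
#'
#' Columns are mean-centered and scaled to unit variance (missing dosages
#' imputed to the column mean; monomorphic columns dropped); the leading
#' left singular vectors scaled by their singular values give the
#' per-sample components.
#'
#' @param genotypes Dosage matrix (samples x SNPs).
#' @param k Number of components.
#' @return Matrix (samples x k) with sample ids as row names and columns
#'   `PC1..PCk`.
#' @export
compute_pcs <- function(genotypes, k = 2L) {
  G <- genotypes
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  v <- apply(G, 2L, stats::var)
  keep <- !is.na(v) & v > 0
  if (sum(keep) < k) stop(sprintf("need >= %d non-monomorphic SNPs", k))
  G <- scale(G[, keep, drop = FALSE])
  sv <- svd(G, nu = k, nv = 0)
  if (k > sum(sv$d > 1e-8)) stop("k exceeds the rank of the genotype matrix")
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(pcs) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  pcs
}

#' Assign samples to ancestry subclusters
#'
#' Three methods: `"kmeans"` clusters the component vectors by k-means
#' under a fixed seed (run on a private RNG stream); `"gate"` applies
#' rectangular gates `params$xlim`/`params$ylim` on the first two
#' components (inside = `"C1"`, outside = `"C0"`); `"labels"` passes
#' `params$labels` through.
#'
#' @param pcs Component matrix from [compute_pcs()].
#' @param method `"kmeans"`, `"gate"` or `"labels"`.
#' @param params List of method parameters: `k` and `seed` for kmeans;
#'   `xlim`, `ylim` for gate; `labels` for labels.
#' @return Character vector of cluster labels named by sample id.
#' @export
assign_cluster <- function(pcs, method = c("kmeans", "gate", "labels"),
                           params = list()) {
  method <- match.arg(method)
  labels <- switch(method,
    kmeans = {
      k <- params$k %||% 2L
      seed <- params$seed %||% 1L
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seed)
      km <- kmeans(pcs, centers = k, nstart = 10L)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
      paste0("C", km$cluster)
    },
    gate = {
      xl <- params$xlim; yl <- params$ylim
      if (is.null(xl) || is.null(yl)) stop("gate method needs xlim and ylim")
      inside <- pcs[, 1L] >= xl[1L] & pcs[, 1L] <= xl[2L] &
        pcs[, 2L] >= yl[1L] & pcs[, 2L] <= yl[2L]
      ifelse(inside, "C1", "C0")
    },
    labels = {
      if (is.null(params$labels) || length(params$labels) != nrow(pcs)) {
        stop("labels method needs one label per sample")
      }
      as.character(params$labels)
    }
  )
  stats::setNames(labels, rownames(pcs))
}

#' Carrier enrichment within an ancestry subcluster
#'
#' Convenience composition of cluster labels with [two_proportion_z()]:
#' among members of `cluster_label`, compares the proportion of
#' rare-variant carriers between cases and controls.
#'
#' @param carriers Sample ids carrying the variant.
#' @param cluster_labels Named cluster labels (see [assign_cluster()]).
#' @param samples Phenotype data.frame (`sample_id`, `status`).
#' @param cluster_label The subcluster to test.
#' @return A `prop_test` (see [two_proportion_z()]).
#' @export
cluster_carrier_test <- function(carriers, cluster_labels, samples,
                                 cluster_label) {
  in_cluster <- samples$sample_id[cluster_labels[samples$sample_id] == cluster_label]
  cases <- intersect(in_cluster, samples$sample_id[samples$status == "case"])
  controls <- intersect(in_cluster, samples$sample_id[samples$status == "control"])
  two_proportion_z(length(intersect(carriers, cases)), length(cases),
                   length(intersect(carriers, controls)), length(controls))
}
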