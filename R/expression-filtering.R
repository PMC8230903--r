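#' Remove genes with low total counts
#'
#' Drops every gene whose total count across all samples is less than or
#' equal to `threshold` (default 10), preserving gene order. This is the
#' first step of the candidate-selection funnel.
#'
#' @param counts a `count_matrix` (see [gen_counts()]) or a plain numeric
#'   matrix with genes in rows.
#' @param threshold total-count threshold; genes with totals `<= threshold`
#'   are removed.
#' @return the same type as the input, restricted to retained genes.
#' @export
filter_low_counts <- function(counts, threshold = 10) {
  if (!is.numeric(threshold) || threshold < 0) stopf("'threshold' must be >= 0")
  if (inherits(counts, "count_matrix")) {
    keep <- rowSums(counts$counts) > threshold
    counts$counts <- counts$counts[keep, , drop = FALSE]
    counts$gene_ids <- counts$gene_ids[keep]
    counts$truth <- counts$truth[keep, , drop = FALSE]
    counts
  } else {
    counts[rowSums(counts) > threshold, , drop = FALSE]
  }
}

#' Median-of-ratios size factors
#'
#' Standard library-size normalization: each sample's size factor is the
#' median across genes of the ratio of its counts to the per-gene geometric
#' mean, computed over genes expressed in all samples.
#'
#' @param counts numeric matrix, genes x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use]))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Negative-binomial differential expression over a stage series
#'
#' Fits, per gene, a negative-binomial GLM (log link) of counts on the
#' developmental stage, with median-of-ratios size factors as offsets. The
#' dispersion is estimated per gene by method of moments within stages
#' (floored at `1e-8`); there is no shrinkage across genes, a documented
#' simplification relative to full DESeq2-style empirical-Bayes machinery.
#' The reported `log2_fold_change` contrasts the last stage against the
#' first; significance is a Wald test on that coefficient, adjusted across
#' genes by Benjamini-Hochberg.
#'
#' @param counts a `count_matrix` or a numeric genes x samples matrix.
#' @param design character vector of stage labels, one per sample (ignored
#'   if `counts` is a `count_matrix`, which carries its own labels).
#' @param contrast `"last_vs_first"` (default) or a length-2 vector
#'   `c(stage_b, stage_a)` giving the numerator and denominator stage.
#' @return data frame of class `de_result` with columns `gene_id`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `mean_count` and
#'   `all_zero`.
#' @export
differential_expression <- function(counts, design = NULL,
                                    contrast = "last_vs_first") {
  if (inherits(counts, "count_matrix")) {
    design <- counts$stage_labels
    counts <- counts$counts
  }
  if (is.null(design)) stopf("'design' stage labels are required")
  design <- as.character(design)
  if (length(design) != ncol(counts)) {
    stopf("'design' must label every sample (%d != %d)",
          length(design), ncol(counts))
  }
  tab <- table(design)
  if (length(tab) < 2L) stopf("at least 2 distinct stages are required")
  if (any(tab < 2L)) {
    stopf("stage '%s' has fewer than 2 replicates", names(tab)[tab < 2][1])
  }
  lev <- unique(design)  # keep sample order as stage order
  if (identical(contrast, "last_vs_first")) {
    contrast <- c(lev[length(lev)], lev[1])
  }
  if (!all(contrast %in% lev)) stopf("contrast stage not present in design")
  stage <- factor(design, levels = c(contrast[2], setdiff(lev, contrast[2])))
  sf <- size_factors(counts)
  off <- log(sf)
  coef_name <- paste0("stage", contrast[1])
  n_genes <- nrow(counts)
  lfc <- numeric(n_genes); pval <- rep(1, n_genes)
  zero <- logical(n_genes)
  norm <- sweep(counts, 2, sf, "/")
  for (i in seq_len(n_genes)) {
    y <- counts[i, ]
    if (all(y == 0)) { zero[i] <- TRUE; next }
    if (length(unique(y)) == 1L && length(unique(off)) == 1L) {
      # identical counts everywhere: no stage effect by construction
      next
    }
    disp <- mom_dispersion(norm[i, ], stage)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ stage + offset(off),
                                  family = MASS::negative.binomial(
                                    theta = 1 / disp))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- summary(fit)$coefficients
    if (!coef_name %in% rownames(cf)) next
    beta <- cf[coef_name, "Estimate"]
    se <- cf[coef_name, "Std. Error"]
    lfc[i] <- beta / log(2)
    if (is.finite(se) && se > 0) {
      pval[i] <- 2 * stats::pnorm(-abs(beta / se))
    }
  }
  res <- data.frame(
    gene_id = rownames(counts) %||% sprintf("g%d", seq_len(n_genes)),
    log2_fold_change = lfc,
    p_value = pval,
    p_adjusted = stats::p.adjust(pval, method = "BH"),
    mean_count = rowMeans(norm),
    all_zero = zero,
    stringsAsFactors = FALSE
  )
  class(res) <- c("de_result", "data.frame")
  res
}

# Method-of-moments NB dispersion from normalized counts, pooled within
# stages so the planted stage effect does not inflate the estimate.
mom_dispersion <- function(x, stage, floor = 1e-8) {
  est <- tapply(x, stage, function(v) {
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    (stats::var(v) - m) / m^2
  })
  d <- mean(est, na.rm = TRUE)
  if (!is.finite(d) || d < floor) floor else d
}

#' Select candidate genes from differential-expression results
#'
#' A gene is a candidate iff `p_adjusted <= padj_max` and
#' `|log2_fold_change| >= lfc_min` (both boundaries inclusive).
#'
#' @param results a [differential_expression()] result.
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 2).
#' @return character vector of selected gene ids (possibly empty).
#' @export
select_candidates <- function(results, padj_max = 0.05, lfc_min = 2) {
  if (!is.numeric(padj_max) || padj_max <= 0) stopf("'padj_max' must be positive")
  if (!is.numeric(lfc_min) || lfc_min <= 0) stopf("'lfc_min' must be positive")
  if (!nrow(results)) return(character(0))
  with(results, gene_id[p_adjusted <= padj_max &
                          abs(log2_fold_change) >= lfc_min])
}
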