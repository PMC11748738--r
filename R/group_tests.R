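#' Prevalence filter
#'
#' Keeps only features observed (value > 0) in at least `min_prevalence` of
#' the samples being compared, the usual guard before two-group testing of
#' sparse gene or taxon tables.
#'
#' @param x samples x features numeric matrix, non-negative.
#' @param min_prevalence minimum presence fraction in (0, 1\]; default 0.30.
#' @return matrix with failing features dropped; attribute `n_removed`
#'   records how many were removed.
#' @export
prevalence_filter <- function(x, min_prevalence = 0.30) {
  if (!(min_prevalence > 0 && min_prevalence <= 1))
    stop("min_prevalence must lie in (0, 1]")
  x <- as.matrix(x)
  prev <- colMeans(x > 0)
  keep <- prev >= min_prevalence
  out <- x[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Tie-corrected normal approximation for the Mann-Whitney U statistic, with
# continuity correction. Returns Z (signed: positive when group 1 tends
# higher) and the approximate two-sided p.
mw_normal <- function(u, n1, n2, tie_counts) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(z = 0, p = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  if (u == mu) z <- 0
  list(z = z, p = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
}

#' Two-group Wilcoxon enrichment test with rank-based effect size
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test per feature between the
#' two levels of `groups`, with the tie-corrected, continuity-corrected
#' normal approximation providing the standardized score Z and the effect
#' size r = |Z| / sqrt(N). For small comparisons (N <= `exact_max_n`)
#' without ties the p-value comes from the exact U distribution instead.
#' P-values are Benjamini-Hochberg corrected across features, and a feature
#' is flagged enriched when q < `alpha` and r >= `min_effect` (double
#' threshold).
#'
#' @param x samples x features matrix (or a vector for a single feature).
#' @param groups two-level factor along samples; each level needs >= 2
#'   samples.
#' @param alpha FDR threshold for the enrichment flag.
#' @param min_effect minimum effect size r for the enrichment flag.
#' @param exact_max_n largest N for which the exact null is used (no ties).
#' @return data.frame per feature: `feature`, `mean_<level>`, `sd_<level>`,
#'   `W` (rank-sum of the first level), `U`, `Z`, `effect_r`, `p`, `q`,
#'   `direction` (level with higher mean rank), `enriched`.
#' @export
wilcoxon_enrichment <- function(x, groups, alpha = 0.05, min_effect = 0.4,
                                exact_max_n = 12) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(NULL, "feature"))
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels, got ", nlevels(groups))
  if (length(groups) != nrow(x))
    stop("groups length must match the number of samples")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  i1 <- groups == g1
  n1 <- sum(i1); n2 <- sum(!i1); n <- n1 + n2

  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (length(unique(v)) == 1) {
      return(data.frame(W = n1 * (n1 + 1) / 2 + n1 * n2 / 2, U = n1 * n2 / 2,
                        Z = 0, effect_r = 0, p = 1,
                        direction = NA_character_))
    }
    r <- rank(v)
    w <- sum(r[i1])                       # rank-sum of group 1
    u <- w - n1 * (n1 + 1) / 2            # Mann-Whitney U of group 1
    ties <- table(v)
    appr <- mw_normal(u, n1, n2, as.numeric(ties))
    p <- if (n <= exact_max_n && all(ties == 1)) {
      if (u > n1 * n2 / 2)
        min(1, 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
      else
        min(1, 2 * stats::pwilcox(u, n1, n2))
    } else appr$p
    data.frame(W = w, U = u, Z = appr$z,
               effect_r = abs(appr$z) / sqrt(n), p = p,
               direction = if (u > n1 * n2 / 2) g1 else if (u < n1 * n2 / 2)
                 g2 else NA_character_)
  })
  res <- do.call(rbind, res)
  out <- data.frame(feature = colnames(x),
                    mean_1 = colMeans(x[i1, , drop = FALSE]),
                    sd_1 = apply(x[i1, , drop = FALSE], 2, stats::sd),
                    mean_2 = colMeans(x[!i1, , drop = FALSE]),
                    sd_2 = apply(x[!i1, , drop = FALSE], 2, stats::sd),
                    res, stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0(c("mean_", "sd_"), g1),
                       paste0(c("mean_", "sd_"), g2))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < alpha & out$effect_r >= min_effect
  rownames(out) <- NULL
  out
}

#' Reads-per-kilobase normalization
#'
#' Divides each gene's read count by its length in kilobases so that genes
#' of different lengths are comparable within a sample.
#'
#' @param gene_counts genes x samples (or samples x genes with
#'   `genes_in_rows = FALSE`) count matrix.
#' @param gene_lengths_bp positive gene lengths in base pairs, parallel to
#'   the gene dimension.
#' @param genes_in_rows whether genes are rows (default TRUE).
#' @return matrix of reads per kilobase, same shape as input.
#' @export
rpk_normalize <- function(gene_counts, gene_lengths_bp,
                          genes_in_rows = TRUE) {
  gene_counts <- as.matrix(gene_counts)
  ngenes <- if (genes_in_rows) nrow(gene_counts) else ncol(gene_counts)
  if (length(gene_lengths_bp) != ngenes)
    stop("gene_lengths_bp length must match the number of genes")
  if (any(gene_lengths_bp <= 0)) stop("gene lengths must be positive")
  kb <- gene_lengths_bp / 1000
  if (genes_in_rows) gene_counts / kb else t(t(gene_counts) / kb)
}
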