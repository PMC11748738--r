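#' Centered log-ratio transform
#'
#' Per sample (row), y_i = ln((x_i + pc) / g(x + pc)) with g the geometric
#' mean over features, so each transformed row sums to zero and the result
#' is invariant to per-sample sequencing depth. A pseudocount of 1 read is
#' added before closure by default; `pseudocount = 0` is accepted only when
#' the matrix holds no zeros.
#'
#' @param counts samples x features matrix, non-negative.
#' @param pseudocount value added to every count before the transform.
#' @return matrix of the same shape; rows sum to 0.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop("no features to transform")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts == 0))
    stop("pseudocount 0 requires strictly positive counts")
  if (any(colSums(counts + pseudocount) == 0))
    stop("all-zero feature set")
  lx <- log(counts + pseudocount)
  sweep(lx, 1, rowMeans(lx), "-")
}

pearson_p <- function(r, n) {
  # two-sided t-test p-value for a Pearson coefficient
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Pearson correlation on CLR-transformed features
#'
#' Standard Pearson correlation between columns of a CLR matrix with a
#' two-sided t-distribution p-value; because the input is CLR-transformed
#' the coefficient is robust to the compositional nature of count data.
#' In all-pairs mode p-values are Benjamini-Hochberg adjusted across the
#' unique pairs.
#'
#' @param clr_matrix samples x features CLR matrix (see [clr_transform()]).
#' @param pair optional length-2 vector of feature names/indices; if given,
#'   a single-row result is returned (no adjustment).
#' @param alpha significance level applied to q (all-pairs) or p (single
#'   pair).
#' @return data.frame `feature1`, `feature2`, `method`, `rho`, `p`, `q`,
#'   `significant`, `zero_variance`.
#' @export
clr_pearson <- function(clr_matrix, pair = NULL, alpha = 0.05) {
  m <- as.matrix(clr_matrix)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples")
  if (any(!is.finite(m))) stop("CLR matrix must be finite")
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (!is.null(pair)) {
    idx <- if (is.character(pair)) match(pair, colnames(m)) else pair
    if (any(is.na(idx))) stop("pair not found among features")
    m <- m[, idx, drop = FALSE]
  }
  v <- apply(m, 2, stats::var)
  pairs <- utils::combn(ncol(m), 2)
  f1 <- colnames(m)[pairs[1, ]]
  f2 <- colnames(m)[pairs[2, ]]
  zv <- v[pairs[1, ]] == 0 | v[pairs[2, ]] == 0
  rho <- mapply(function(i, j)
    if (v[i] == 0 || v[j] == 0) NA_real_ else stats::cor(m[, i], m[, j]),
    pairs[1, ], pairs[2, ])
  p <- ifelse(is.na(rho), NA_real_, pearson_p(rho, n))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature1 = f1, feature2 = f2, method = "clr_pearson",
             rho = rho, p = p, q = q,
             significant = !is.na(q) &
               (if (is.null(pair)) q else p) < alpha,
             zero_variance = unname(zv),
             stringsAsFactors = FALSE)
}

#' Proportionality coefficient rho
#'
#' Symmetric association measure for compositional data:
#' rho(i, j) = 1 - var(y_i - y_j) / (var(y_i) + var(y_j))
#'           = 2 cov(y_i, y_j) / (var(y_i) + var(y_j))
#' on CLR-transformed values, equal to 1 for identical columns and bounded
#' by \[-1, 1\].
#'
#' @param clr_matrix samples x features CLR matrix.
#' @return features x features matrix, diagonal exactly 1; pairs where both
#'   variances are zero are NA.
#' @export
proportionality_rho <- function(clr_matrix) {
  m <- as.matrix(clr_matrix)
  if (nrow(m) < 3) stop("need at least 3 samples")
  v <- apply(m, 2, stats::var)
  cv <- stats::cov(m)
  denom <- outer(v, v, "+")
  rho <- 2 * cv / denom
  rho[denom == 0] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Permutation FDR cutoff for proportionality coefficients
#'
#' Builds a null by independently permuting every feature column across
#' samples `n_perm` times and recomputing the pairwise coefficients. For
#' each cutoff c on a grid of step `step`, FDR(c) is the mean over
#' permutations of the number of null pairs with |rho| >= c divided by the
#' number of observed pairs with |rho| >= c (at least 1). The smallest
#' cutoff achieving FDR <= alpha is returned; when none does (as on data
#' that is itself exchangeable), the cutoff is reported unattainable.
#'
#' @param clr_matrix samples x features CLR matrix.
#' @param alpha target false discovery rate.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @param step grid step for candidate cutoffs.
#' @return list: `cutoff` (numeric or NA), `attainable`, `table`
#'   (data.frame cutoff, n_observed, mean_null, fdr).
#' @export
fdr_cutoff <- function(clr_matrix, alpha = 0.05, n_perm = 100, seed = 1,
                       step = 0.05) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  m <- as.matrix(clr_matrix)
  obs <- abs(proportionality_rho(m)[upper.tri(diag(ncol(m)))])
  grid <- seq(step, 1, by = step)
  null_counts <- matrix(0, n_perm, length(grid))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- apply(m, 2, sample)
    nr <- abs(proportionality_rho(perm)[upper.tri(diag(ncol(m)))])
    null_counts[b, ] <- vapply(grid, function(cc)
      sum(nr >= cc, na.rm = TRUE), numeric(1))
  }
  n_obs <- vapply(grid, function(cc) sum(obs >= cc, na.rm = TRUE), numeric(1))
  fdr <- pmin(1, colMeans(null_counts) / pmax(1, n_obs))
  # a cutoff only counts as attained when it retains at least one observed
  # pair; vacuous cutoffs beyond the data are not a discovery threshold
  ok <- which(fdr <= alpha & n_obs >= 1)
  cutoff <- if (length(ok)) grid[min(ok)] else NA_real_
  list(cutoff = cutoff, attainable = length(ok) > 0,
       table = data.frame(cutoff = grid, n_observed = n_obs,
                          mean_null = colMeans(null_counts), fdr = fdr))
}

#' PCA on the CLR-transformed species table
#'
#' Species whose overall mean relative abundance falls below
#' `min_abundance_pct` percent are removed first (spurious low-abundance
#' hits), then the table is CLR-transformed and decomposed by centered
#' singular value decomposition. Component signs follow a fixed convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param table a [species_table] (species-level rows are used) or a plain
#'   samples x features count matrix.
#' @param min_abundance_pct filter threshold on mean relative abundance, in
#'   percent of species-level reads.
#' @param pseudocount passed to [clr_transform()].
#' @param n_components number of components to keep (default all).
#' @return list `scores` (samples x K), `loadings` (features x K),
#'   `explained_variance` (fractions, non-increasing), `kept_features`.
#' @export
clr_pca <- function(table, min_abundance_pct = 0.001, pseudocount = 1,
                    n_components = NULL) {
  counts <- if (inherits(table, "species_table")) {
    sp <- species_level(table)
    m <- t(sp$counts)
    colnames(m) <- taxon_names(sp)$species
    m
  } else as.matrix(table)
  rel <- 100 * counts / pmax(rowSums(counts), 1)
  keep <- colMeans(rel) >= min_abundance_pct
  if (sum(keep) < 2) stop("fewer than 2 features pass the abundance filter")
  counts <- counts[, keep, drop = FALSE]
  y <- clr_transform(counts, pseudocount)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sv <- svd(yc)
  k <- if (is.null(n_components)) ncol(sv$v) else min(n_components, ncol(sv$v))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {        # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  dimnames(scores) <- list(rownames(counts), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(counts), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)],
       kept_features = colnames(counts))
}

#' Canonical correlation screening of metadata against clade shares
#'
#' For every metadata variable, the first canonical correlation between the
#' variable's design matrix (indicator columns for categorical variables,
#' reference level dropped) and a block of clade-share columns, with a
#' permutation p-value obtained by shuffling sample labels of the variable.
#' Following the conventional screening rule, a variable is flagged
#' significant when the canonical correlation is at least `min_cc` and the
#' permutation p-value is at most `max_p`.
#'
#' @param metadata data.frame of variables (rows aligned with `block`).
#' @param block numeric matrix of clade shares, samples in rows.
#' @param variables columns of `metadata` to test (default: all).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param min_cc,max_p significance rule (defaults 0.4 and 0.01).
#' @return data.frame `variable`, `cc`, `p`, `n`, `significant`, `constant`.
#' @export
cancor_pairs <- function(metadata, block, variables = colnames(metadata),
                         n_perm = 999, seed = 1, min_cc = 0.4,
                         max_p = 0.01) {
  block <- as.matrix(block)
  if (nrow(block) != nrow(metadata))
    stop("metadata and block must have the same number of rows")
  first_cc <- function(X, Y) {
    cc <- tryCatch(stats::cancor(X, Y), error = function(e) NULL)
    if (is.null(cc) || !length(cc$cor)) NA_real_ else cc$cor[1]
  }
  set.seed(seed)
  out <- lapply(variables, function(v) {
    x <- metadata[[v]]
    ok <- !is.na(x) & stats::complete.cases(block)
    n <- sum(ok)
    if (n < 5)
      return(data.frame(variable = v, cc = NA_real_, p = NA_real_, n = n,
                        significant = FALSE, constant = FALSE))
    xv <- x[ok]
    if (length(unique(xv)) < 2)
      return(data.frame(variable = v, cc = NA_real_, p = NA_real_, n = n,
                        significant = FALSE, constant = TRUE))
    X <- stats::model.matrix(~x, data.frame(x = xv))[, -1, drop = FALSE]
    Y <- block[ok, , drop = FALSE]
    cc_obs <- first_cc(X, Y)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      cc_b <- first_cc(X[sample(nrow(X)), , drop = FALSE], Y)
      if (!is.na(cc_b) && cc_b >= cc_obs) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    data.frame(variable = v, cc = cc_obs, p = p, n = n,
               significant = !is.na(cc_obs) && cc_obs >= min_cc && p <= max_p,
               constant = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
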