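test_that("CLR rows center to zero and the transform is scale invariant", {
  m <- matrix(c(5, 5, 5,  2, 4, 8), nrow = 2, byrow = TRUE)
  y <- clr_transform(m, pseudocount = 0)
  expect_equal(y[1, ], c(0, 0, 0))
  expect_equal(y[2, ], c(log(0.5), 0, log(2)))   # geometric mean 4
  y2 <- clr_transform(m * 10, pseudocount = 0)
  expect_equal(y, y2)
  set.seed(1)
  r <- matrix(rpois(60, 40) + 1, 6)
  expect_equal(rowSums(clr_transform(r)), rep(0, 6), tolerance = 1e-10)
})

test_that("CLR rejects invalid input", {
  expect_error(clr_transform(matrix(-1, 2, 2)), "non-negative")
  expect_error(clr_transform(matrix(c(0, 1, 1, 1), 2), pseudocount = 0),
               "strictly positive")
})

test_that("clr_pearson matches the textbook covariance formula", {
  y <- matrix(c(1.2, -0.3, 0.8, 2.1, -1.5,
                0.7, 0.1, 1.9, -0.6, 0.4), ncol = 2)
  colnames(y) <- c("a", "b")
  res <- clr_pearson(y, pair = c("a", "b"))
  # independent recomputation from first principles
  rho_oracle <- sum((y[, 1] - mean(y[, 1])) * (y[, 2] - mean(y[, 2]))) /
    sqrt(sum((y[, 1] - mean(y[, 1]))^2) * sum((y[, 2] - mean(y[, 2]))^2))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
  # perfect linear relation
  x <- rnorm(10)
  expect_equal(clr_pearson(cbind(a = x, b = 2 * x + 1))$rho, 1)
})

test_that("zero-variance columns are flagged NA rather than failing", {
  y <- cbind(a = rnorm(6), b = rep(1, 6))
  res <- clr_pearson(y)
  expect_true(is.na(res$rho))
  expect_true(res$zero_variance)
})

test_that("proportionality rho satisfies both algebraic forms and bounds", {
  set.seed(3)
  y <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, letters[1:4]))
  rho <- proportionality_rho(y)
  # dual-formula oracle: 1 - var(y_i - y_j) / (var_i + var_j)
  for (i in 1:4) for (j in 1:4) {
    alt <- 1 - var(y[, i] - y[, j]) / (var(y[, i]) + var(y[, j]))
    expect_equal(rho[i, j], alt, tolerance = 1e-12)
  }
  expect_equal(diag(rho), rep(1, 4), ignore_attr = TRUE)
  expect_identical(rho, t(rho))
  # identical and sign-flipped columns hit the extremes
  z <- rnorm(8)
  rho2 <- proportionality_rho(cbind(a = z, b = z, c = -z))
  expect_equal(rho2["a", "b"], 1)
  expect_equal(rho2["a", "c"], -1)
})

test_that("the permutation FDR cutoff behaves at the extremes", {
  set.seed(10)
  # exchangeable data: no cutoff attains 5% FDR in the vast majority of
  # runs (the observed maximum is itself exchangeable with the permutation
  # null, so a few percent of runs attain a vacuously high cutoff)
  unattain <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    null_y <- matrix(rnorm(20 * 12), 20, 12)
    !fdr_cutoff(null_y, alpha = 0.05, n_perm = 40, seed = s)$attainable
  }, logical(1))
  expect_gte(mean(unattain), 0.9)
  # a planted proportional pair survives the selected cutoff
  set.seed(11)
  base <- rnorm(30)
  y <- cbind(p1 = base, p2 = base + rnorm(30, sd = 0.05),
             matrix(rnorm(30 * 6), 30, 6))
  fc <- fdr_cutoff(y, alpha = 0.05, n_perm = 50, seed = 2)
  expect_true(fc$attainable)
  expect_gte(abs(proportionality_rho(y)["p1", "p2"]), fc$cutoff)
  # vacuous control returns the smallest grid value
  set.seed(99)
  any_y <- matrix(rnorm(20 * 8), 20, 8)
  expect_equal(fdr_cutoff(any_y, alpha = 1, n_perm = 5, seed = 1)$cutoff,
               0.05)
  expect_error(fdr_cutoff(any_y, n_perm = 0), "n_perm")
})

test_that("CLR-PCA filters, matches the eigen oracle, and fixes signs", {
  set.seed(4)
  counts <- matrix(rpois(10 * 6, 200), 10, 6,
                   dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  # a feature far below 0.001% mean abundance is dropped
  counts <- cbind(counts, rare = c(1, rep(0, 9)) * 0)
  counts[1, "rare"] <- 0   # all-zero: mean abundance 0 < threshold
  res <- clr_pca(counts, min_abundance_pct = 0.001)
  expect_false("rare" %in% res$kept_features)
  # variance fractions are non-increasing in [0, 1]
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  expect_true(all(res$explained_variance >= 0 &
                    res$explained_variance <= 1))
  # eigen-decomposition oracle on the CLR covariance
  y <- clr_transform(counts[, res$kept_features], 1)
  ev <- eigen(cov(y), symmetric = TRUE)$values
  comp_var <- apply(res$scores, 2, var)
  expect_equal(comp_var[1:4], ev[1:4], tolerance = 1e-8,
               ignore_attr = TRUE)
  # the dominant loading of each component is positive
  for (j in seq_len(ncol(res$loadings)))
    expect_gte(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  # duplicated samples get identical scores
  dup <- rbind(counts[, 1:6], counts[1, 1:6, drop = FALSE])
  rd <- clr_pca(dup, min_abundance_pct = 0.001)
  expect_equal(rd$scores[1, ], rd$scores[11, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("canonical correlations recover exact and regression oracles", {
  set.seed(6)
  block <- matrix(rnorm(40 * 3), 40, 3)
  md <- data.frame(exact = block[, 2], cont = rnorm(40))
  res <- cancor_pairs(md, block, n_perm = 49, seed = 1)
  expect_equal(res$cc[res$variable == "exact"], 1, tolerance = 1e-8)
  # single continuous variable: cc equals sqrt(R^2) of its regression on
  # the block
  r2 <- summary(lm(md$cont ~ block))$r.squared
  expect_equal(res$cc[res$variable == "cont"], sqrt(r2), tolerance = 1e-8)
})

test_that("constant or scarce metadata variables are flagged, not fatal", {
  block <- matrix(rnorm(20 * 2), 20, 2)
  md <- data.frame(const = rep("x", 20),
                   scarce = c(rep(NA, 17), 1, 2, 3))
  res <- cancor_pairs(md, block, n_perm = 9, seed = 1)
  expect_true(res$constant[res$variable == "const"])
  expect_true(is.na(res$cc[res$variable == "scarce"]))
  expect_false(any(res$significant))
})

test_that("an independent variable is almost never called significant", {
  # type-I Monte-Carlo check of the cc >= 0.4 & p <= 0.01 rule
  set.seed(8)
  flags <- vapply(1:150, function(b) {
    block <- matrix(rnorm(100 * 5), 100, 5)
    md <- data.frame(v = rnorm(100))
    cancor_pairs(md, block, n_perm = 199, seed = b)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.02)
})
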