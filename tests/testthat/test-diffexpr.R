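toy_ct <- function(counts, conds = c("0Se", "0Se", "0.1Se", "0.1Se"),
                   lib_sizes = NULL) {
  m <- as.matrix(counts)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  count_table(m, data.frame(sample_id = colnames(m), condition = conds),
              lib_sizes)
}

test_that("CPM filtering keeps genes above 1 CPM in at least 3 samples", {
  libs <- rep(1e7, 4)
  # CPM of (1.2, 1.5, 0.3, 2.0) at 1e7-read libraries
  m <- rbind(zero = c(0L, 0L, 0L, 0L),
             keep = c(12L, 15L, 3L, 20L),
             lose = c(50L, 0L, 0L, 0L))
  ct <- toy_ct(m, lib_sizes = libs)
  out <- cpm_filter(ct)
  expect_identical(rownames(out$counts), "keep")
  expect_error(cpm_filter(toy_ct(m[, 1:2], conds = c("a", "b"),
                                 lib_sizes = libs[1:2])), "unsatisfiable")
})

test_that("CPM filtering matches a brute-force row scan on random tables", {
  set.seed(70)
  m <- matrix(rnbinom(200 * 6, mu = 2, size = 1), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  ct <- toy_ct(m, conds = rep(c("0Se", "0.1Se"), each = 3))
  out <- cpm_filter(ct)
  libs <- colSums(m)
  brute <- rownames(m)[vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] / libs * 1e6 > 1) >= 3, TRUE)]
  expect_identical(rownames(out$counts), brute)
  # never removes a gene whose minimum CPM exceeds 1
  always <- rownames(m)[apply(sweep(m, 2, libs / 1e6, "/"), 1, min) > 1]
  expect_true(all(always %in% rownames(out$counts)))
})

test_that("TMM factors are 1 for identical columns and recover scaling", {
  set.seed(71)
  x <- rnbinom(500, mu = 100, size = 10)
  expect_equal(unname(tmm_factors(cbind(x, x))), c(1, 1))
  # doubling a column is a pure library-size effect: factors stay ~1 and the
  # effective library-size ratio is recovered within 1%
  y <- cbind(x, 2L * x)
  f <- tmm_factors(y)
  eff_ratio <- (colSums(y)[2] * f[2]) / (colSums(y)[1] * f[1])
  expect_lt(abs(eff_ratio - 2), 0.02)
})

test_that("TMM factors agree with the edgeR reference implementation", {
  set.seed(72)
  mu <- rexp(1500, 1 / 150)
  depth <- c(1, 1.6, 0.6, 1.3)
  y <- sapply(1:4, function(j) rnbinom(1500, mu = mu * depth[j], size = 5))
  # plant asymmetric DE so the trimming matters
  y[1:80, 3:4] <- y[1:80, 3:4] * 6L
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
  f <- unname(tmm_factors(y))
  expect_true(all(abs(f - f_ref) / f_ref < 0.05))
})

test_that("common dispersion is recovered from null NB data", {
  set.seed(73)
  y <- matrix(rnbinom(3000 * 4, mu = 150, size = 10), ncol = 4)
  grp <- factor(c("a", "a", "b", "b"))
  d <- estimate_common_dispersion(y, grp)
  expect_lt(abs(d - 0.1), 0.02)
  # Poisson data: estimate collapses to (near) zero
  yp <- matrix(rpois(3000 * 4, 150), ncol = 4)
  expect_lt(estimate_common_dispersion(yp, grp), 0.005)
})

test_that("exact NB test has binomial and null limits and label symmetry", {
  grp <- factor(c("a", "b"))
  # balanced counts, dispersion 0, symmetric totals -> p = 1
  p_null <- nb_exact_test(matrix(c(7, 7), 1), grp, dispersion = 0,
                          lib_sizes = c(100, 100))$p
  expect_equal(p_null, 1)
  # all-zero gene -> p = 1
  p_zero <- nb_exact_test(matrix(c(0, 0), 1), grp, dispersion = 0.1,
                          lib_sizes = c(100, 100))$p
  expect_equal(p_zero, 1)
  # dispersion 0, counts 10 vs 0, equal libraries: two-sided binomial exact
  p10 <- nb_exact_test(matrix(c(10, 0), 1), grp, dispersion = 0,
                       lib_sizes = c(100, 100))$p
  p_binom <- sum(dbinom(0:10, 10, 0.5)[dbinom(0:10, 10, 0.5) <=
                                       dbinom(10, 10, 0.5) * (1 + 1e-9)])
  expect_equal(p10, p_binom)
  expect_equal(p10, 2 / 1024)
  # symmetry under group-label swap
  set.seed(74)
  y <- matrix(rnbinom(200 * 4, mu = 80, size = 8), ncol = 4)
  g1 <- factor(c("a", "a", "b", "b")); g2 <- factor(c("b", "b", "a", "a"))
  expect_equal(nb_exact_test(y, g1, dispersion = 0.1)$p,
               nb_exact_test(y, g2, dispersion = 0.1)$p)
})

test_that("null type-I error is calibrated at the 5 percent level", {
  set.seed(75)
  y <- matrix(rnbinom(1e4 * 4, mu = 200, size = 10), ncol = 4)
  grp <- factor(c("a", "a", "b", "b"))
  p <- nb_exact_test(y, grp)$p
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("BH adjustment equals the hand-computed step-up", {
  expect_equal(bh_fdr(0.04), 0.04)
  # step-up by hand: p_(i) * n / i with cumulative minimum from the top
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.002, 0.02, 0.9)), c(0.006, 0.03, 0.9))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # monotone in p-value order and permutation-invariant
  set.seed(76)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), adj[perm])
})

test_that("DE calls require both the fold and the FDR threshold", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    fold = c(1.4, 2.0, 0.5, 2.0),
                    fdr = c(0.01, 0.04, 0.04, 0.2))
  out <- call_de(res)
  expect_identical(out$is_de[match(c("a", "b", "c", "d"), out$gene)],
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("planted four-fold effects are detected with FDR control", {
  set.seed(77)
  n <- 2000; n_de <- 60
  mu <- rep(200, n)
  y <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 50))
  y[1:n_de, 3:4] <- rnbinom(n_de * 2, mu = 800, size = 50)
  rownames(y) <- sprintf("g%04d", 1:n)
  ct <- toy_ct(y)
  res <- de_analysis(ct)
  called <- res$gene[res$is_de]
  planted <- sprintf("g%04d", 1:n_de)
  expect_gt(mean(planted %in% called), 0.95)
  fp <- setdiff(called, planted)
  # false positives among calls stay near the FDR target (binomial slack)
  expect_lt(length(fp), max(5, 0.1 * length(called)))
})

test_that("replicate correlation of normalized CPM is reported per condition", {
  set.seed(78)
  mu <- rexp(800, 1 / 200)
  y <- sapply(1:4, function(j) rnbinom(800, mu = mu + 20, size = 50))
  ct <- toy_ct(y)
  rc <- replicate_correlation(ct)
  expect_identical(nrow(rc), 2L)
  expect_true(all(rc$r_squared > 0.8))
})
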