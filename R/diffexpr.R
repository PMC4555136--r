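#' Count table container
#'
#' Genes x samples integer counts with a sample sheet. Library sizes default
#' to column sums.
#'
#' @param counts integer matrix, rownames = genes, colnames = sample ids
#' @param samples data.frame with columns sample_id, condition (and
#'   optionally replicate), one row per column of `counts`
#' @param lib_sizes optional per-sample library size override
#' @return list of class `count_table`
#' @export
count_table <- function(counts, samples, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(sort(colnames(counts)), sort(samples$sample_id)))
    stop("sample sheet does not match count columns")
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  structure(list(counts = counts, samples = samples,
                 lib_sizes = as.numeric(lib_sizes)),
            class = "count_table")
}

#' Counts per million mapped reads
#' @param counts matrix
#' @param lib_sizes per-sample totals (default column sums)
#' @return matrix of CPM values
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  sweep(counts, 2, lib_sizes / 1e6, "/")
}

#' Expression filter: CPM above threshold in enough samples
#'
#' Retains genes with more than `threshold` counts per million mapped reads
#' in at least `min_samples` samples.
#'
#' @param ct [count_table()]
#' @param threshold CPM threshold (default 1)
#' @param min_samples minimum number of samples above threshold (default 3)
#' @return filtered [count_table()] (library sizes are kept, not recomputed)
#' @export
cpm_filter <- function(ct, threshold = 1, min_samples = 3L) {
  if (ncol(ct$counts) < min_samples)
    stop("fewer than ", min_samples, " samples: the filter is unsatisfiable")
  keep <- rowSums(cpm(ct$counts, ct$lib_sizes) > threshold) >= min_samples
  structure(list(counts = ct$counts[keep, , drop = FALSE],
                 samples = ct$samples, lib_sizes = ct$lib_sizes),
            class = "count_table")
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors for count data: for each sample against a
#' reference (the sample whose upper-quartile count fraction is closest to
#' the mean upper quartile), gene-wise log ratios M and average log
#' abundances A are computed over genes expressed in both; the 30 percent
#' most extreme M and 5 percent most extreme A are trimmed, and the factor
#' is two to the inverse-variance-weighted mean of the remaining M values.
#' Factors are normalized to geometric mean one.
#'
#' @param ct [count_table()] (or a bare count matrix)
#' @param lib_sizes library sizes when `ct` is a matrix
#' @param logratio_trim,abundance_trim trim fractions for M and A
#' @return named numeric vector of factors, one per sample
#' @export
tmm_factors <- function(ct, lib_sizes = NULL, logratio_trim = 0.3,
                        abundance_trim = 0.05) {
  if (inherits(ct, "count_table")) {
    y <- ct$counts; N <- ct$lib_sizes
  } else {
    y <- as.matrix(ct)
    N <- if (is.null(lib_sizes)) colSums(y) else lib_sizes
  }
  ns <- ncol(y)
  if (ns < 2) stop("TMM needs at least two samples")
  f75 <- apply(y, 2, function(col) stats::quantile(col, 0.75)) / N
  if (all(f75 == 0)) {
    warning("degenerate count table; returning unit factors")
    return(stats::setNames(rep(1, ns), colnames(y)))
  }
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ns)
  for (j in seq_len(ns)) {
    fac[j] <- tmm_pair(y[, j], y[, ref], N[j], N[ref],
                       logratio_trim, abundance_trim)
  }
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(y))
}

tmm_pair <- function(obs, ref, No, Nr, lr_trim, ab_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) < 2) {
    warning("too few co-expressed genes for TMM; factor set to 1")
    return(1)
  }
  M <- log2((obs / No) / (ref / Nr))
  A <- 0.5 * log2((obs / No) * (ref / Nr))
  v <- (No - obs) / (No * obs) + (Nr - ref) / (Nr * ref)  # delta-method var of M
  n <- length(M)
  loM <- floor(n * lr_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * ab_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) return(1)
  2^f
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Library sizes are first equalized by quantile-to-quantile mapping of each
#' count to a common (geometric-mean) library size under the current
#' dispersion ("pseudo counts"); the common dispersion then maximizes the
#' conditional log likelihood of the pseudo counts given each gene's group
#' totals, summed over genes and groups. The mapping and the estimate are
#' iterated to convergence.
#'
#' @param counts genes x samples matrix
#' @param group two-level factor over samples
#' @param lib_sizes library sizes (default column sums)
#' @param factors normalization factors (default 1)
#' @param iterations pseudo-count / estimate refinement rounds
#' @return dispersion estimate (0 = Poisson)
#' @export
estimate_common_dispersion <- function(counts, group,
                                       lib_sizes = colSums(counts),
                                       factors = rep(1, ncol(counts)),
                                       iterations = 3L) {
  group <- as.factor(group)
  eff <- lib_sizes * factors
  disp <- 0.01
  for (it in seq_len(iterations)) {
    ps <- pseudo_counts(counts, eff, disp)
    ll <- function(ldisp) cond_loglik(ps$pseudo, group, exp(ldisp))
    opt <- stats::optimize(ll, interval = log(c(1e-6, 5)), maximum = TRUE)
    # compare against the Poisson boundary
    disp_new <- if (cond_loglik(ps$pseudo, group, 1e-8) >= opt$objective)
      0 else exp(opt$maximum)
    if (abs(disp_new - disp) < 1e-4) { disp <- disp_new; break }
    disp <- disp_new
  }
  disp
}

cond_loglik <- function(pseudo, group, disp) {
  r <- 1 / disp
  total <- 0
  for (lev in levels(group)) {
    y <- pseudo[, group == lev, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    total <- total + sum(rowSums(lgamma(y + r)) + lgamma(n * r) -
                         lgamma(z + n * r) - n * lgamma(r))
  }
  total
}

pseudo_counts <- function(counts, eff, disp) {
  Nc <- exp(mean(log(eff)))
  p_g <- rowSums(counts) / sum(eff)
  pseudo <- counts
  for (j in seq_len(ncol(counts))) {
    mu_in <- p_g * eff[j]
    mu_out <- p_g * Nc
    y <- counts[, j]
    if (disp < 1e-8) {
      u <- 0.5 * (stats::ppois(y - 1, mu_in) + stats::ppois(y, mu_in))
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      pseudo[, j] <- stats::qpois(u, mu_out)
    } else {
      r <- 1 / disp
      u <- 0.5 * (stats::pnbinom(y - 1, mu = mu_in, size = r) +
                  stats::pnbinom(y, mu = mu_in, size = r))
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      pseudo[, j] <- stats::qnbinom(u, mu = mu_out, size = r)
    }
    zero <- mu_in == 0
    pseudo[zero, j] <- 0
  }
  list(pseudo = pseudo, common_lib = Nc)
}

#' Exact negative-binomial test for a two-group comparison
#'
#' Per-gene two-sided exact test conditioned on the gene's total pseudo
#' count after library-size equalization: under the null the two group sums
#' are negative binomial with a shared per-sample mean and the common
#' dispersion, and the p-value is the probability of all splits of the
#' total as extreme (as improbable) as the observed one. In the
#' dispersion-to-zero limit this is the two-sided binomial exact test.
#' Symmetric under group-label swap. All-zero genes get p = 1.
#'
#' @param counts genes x samples matrix
#' @param group two-level factor
#' @param dispersion common dispersion; estimated by
#'   [estimate_common_dispersion()] when NULL
#' @param lib_sizes,factors as in [estimate_common_dispersion()]
#' @return data.frame (gene, logFC, fold, p); logFC is computed from the
#'   equalized group means with a half-count prior.
#' @export
nb_exact_test <- function(counts, group, dispersion = NULL,
                          lib_sizes = colSums(counts),
                          factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  eff <- lib_sizes * factors
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, group, lib_sizes, factors)
  ps <- pseudo_counts(counts, eff, dispersion)$pseudo
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  s1 <- round(rowSums(ps[, g1, drop = FALSE]))
  s2 <- round(rowSums(ps[, !g1, drop = FALSE]))
  p <- vapply(seq_along(s1), function(i)
    exact_nb_pvalue(s1[i], s2[i], n1, n2, dispersion), 0)
  logFC <- log2((s2 / n2 + 0.5) / (s1 / n1 + 0.5))  # second level vs first
  data.frame(gene = rownames(counts), logFC = logFC, fold = 2^logFC, p = p,
             stringsAsFactors = FALSE)
}

exact_nb_pvalue <- function(s1, s2, n1, n2, disp) {
  t <- s1 + s2
  if (t == 0) return(1)
  x <- 0:t
  if (disp < 1e-8) {
    logp <- stats::dbinom(x, t, n1 / (n1 + n2), log = TRUE)
  } else {
    lambda <- t / (n1 + n2)
    logp <- stats::dnbinom(x, mu = n1 * lambda, size = n1 / disp, log = TRUE) +
            stats::dnbinom(t - x, mu = n2 * lambda, size = n2 / disp, log = TRUE)
  }
  pobs <- logp[s1 + 1]
  keep <- logp <= pobs + 1e-10
  exp(logsumexp(logp[keep]) - logsumexp(logp))
}

logsumexp <- function(lx) {
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with input checks;
#' monotone in the p-value order and permutation-invariant.
#'
#' @param pvalues numeric vector in [0, 1]
#' @return adjusted values, same order as input
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression calls at the study thresholds
#'
#' A gene is differentially expressed iff its normalized fold change exceeds
#' 1.5 in either direction and its BH false discovery rate is below 0.05.
#'
#' @param results data.frame with columns `fold` and `fdr` (e.g. from
#'   [de_analysis()])
#' @param fold_threshold,fdr_threshold call thresholds
#' @return `results` with an `is_de` flag, ranked by fold change (up first)
#' @export
call_de <- function(results, fold_threshold = 1.5, fdr_threshold = 0.05) {
  results$is_de <- !is.na(results$fdr) &
    (results$fold > fold_threshold | results$fold < 1 / fold_threshold) &
    results$fdr < fdr_threshold
  results[order(-results$fold), ]
}

#' Full count-based differential expression analysis
#'
#' CPM filter, TMM factors, common-dispersion exact negative-binomial test,
#' BH adjustment and threshold calls.
#'
#' @param ct [count_table()]
#' @param numerator,denominator condition labels compared
#'   (numerator-vs-denominator fold changes)
#' @param cpm_threshold,min_samples expression filter parameters
#' @param fold_threshold,fdr_threshold call thresholds
#' @return data.frame (gene, logFC, fold, p, fdr, is_de), ranked by fold
#' @export
de_analysis <- function(ct, numerator = "0.1Se", denominator = "0Se",
                        cpm_threshold = 1, min_samples = 3L,
                        fold_threshold = 1.5, fdr_threshold = 0.05) {
  ct <- cpm_filter(ct, cpm_threshold, min_samples)
  use <- ct$samples$condition %in% c(numerator, denominator)
  counts <- ct$counts[, use, drop = FALSE]
  grp <- factor(ct$samples$condition[use], levels = c(denominator, numerator))
  fac <- tmm_factors(count_table(counts, ct$samples[use, ],
                                 ct$lib_sizes[use]))
  res <- nb_exact_test(counts, grp, lib_sizes = ct$lib_sizes[use],
                       factors = fac)
  res$fdr <- bh_fdr(res$p)
  call_de(res, fold_threshold, fdr_threshold)
}

#' Between-replicate correlation of normalized CPM
#'
#' QC check: squared Pearson correlation of log2 normalized CPM between each
#' pair of biological replicates within a condition.
#'
#' @param ct [count_table()]
#' @param factors normalization factors (default TMM)
#' @param prior pseudo-CPM added before log
#' @return data.frame (condition, sample_a, sample_b, r_squared)
#' @export
replicate_correlation <- function(ct, factors = tmm_factors(ct), prior = 0.5) {
  x <- log2(cpm(ct$counts, ct$lib_sizes * factors) + prior)
  out <- list()
  for (cond in unique(ct$samples$condition)) {
    ids <- ct$samples$sample_id[ct$samples$condition == cond]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(prs))) {
      r2 <- stats::cor(x[, prs[1, k]], x[, prs[2, k]])^2
      out[[length(out) + 1]] <- data.frame(condition = cond,
                                           sample_a = prs[1, k],
                                           sample_b = prs[2, k],
                                           r_squared = r2)
    }
  }
  do.call(rbind, out)
}
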