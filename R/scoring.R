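# Activity scoring: per-gene z-scores, signature z-mean scores, random-set
# null benchmarking, polynomial activity-vs-anchor trend, recovery-curve
# single-cell scoring, and group comparisons.

#' Per-gene z-score transform
#'
#' Each gene row is centred and scaled across samples using the sample
#' standard deviation (n - 1 denominator). Zero-variance rows become all-zero
#' with a warning, keeping sample scores comparable.
#'
#' @param matrix gene x sample matrix (>= 2 samples).
#' @return matrix of the same shape.
#' @export
zscore_by_gene <- function(matrix) {
  x <- unclass(matrix)
  if (ncol(x) < 2L) stop("z-scoring needs >= 2 samples")
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance gene(s) set to z = 0", sum(zero)))
    sd[zero] <- 1
  }
  z <- (x - mu) / sd
  z[zero, ] <- 0
  z
}

#' Signature activity score
#'
#' The per-sample activity is the unweighted mean of gene-wise z-scored
#' expression over the signature genes present in the matrix.
#'
#' @param matrix gene x sample `ExpressionMatrix` (log scale).
#' @param signature character vector of gene ids, or a `GeneSignature`.
#' @param zscored set to `TRUE` if `matrix` is already gene z-scored.
#' @return an `ActivityScores` named numeric vector with attributes
#'   `n_genes_used` and `n_genes_missing`.
#' @export
activity_score <- function(matrix, signature, zscored = FALSE) {
  genes <- if (inherits(signature, "GeneSignature")) signature$genes else as.character(signature)
  genes <- unique(genes)
  present <- intersect(genes, rownames(matrix))
  n_missing <- length(genes) - length(present)
  if (length(present) == 0L) stop("no signature gene present in the matrix")
  if (n_missing > length(genes) / 2) {
    warning(sprintf("%d of %d signature genes missing from the matrix",
                    n_missing, length(genes)))
  }
  z <- if (zscored) unclass(matrix) else zscore_by_gene(matrix)
  scores <- colMeans(z[present, , drop = FALSE])
  structure(scores, n_genes_used = length(present), n_genes_missing = n_missing,
            class = "ActivityScores")
}

#' @export
print.ActivityScores <- function(x, ...) {
  cat(sprintf("ActivityScores: %d samples (genes used: %d, missing: %d)\n",
              length(x), attr(x, "n_genes_used"), attr(x, "n_genes_missing")))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Empirical p-value with the +1 correction
#'
#' `(1 + #\{null >= observed\}) / (n + 1)`; never zero.
#'
#' @param observed observed statistic.
#' @param null vector of null statistic values.
#' @return empirical p in (0, 1].
#' @export
empirical_p <- function(observed, null) {
  (1 + sum(null >= observed)) / (length(null) + 1)
}

#' Random-gene-set null benchmarking
#'
#' Draws `n_iter` uniform gene sets of `set_size` from the matrix universe
#' (without replacement within a draw), applies `statistic_fn` to the
#' activity scores of each random set, and locates the observed statistic in
#' the resulting null distribution.
#'
#' @param matrix gene x sample `ExpressionMatrix`.
#' @param set_size size of each random set.
#' @param n_iter number of iterations (>= 1).
#' @param statistic_fn function of an `ActivityScores` vector returning one
#'   number (e.g. correlation with anchor expression).
#' @param seed integer seed.
#' @param observed optional observed statistic to benchmark.
#' @return a `NullDistribution`: values, summary (mean, sd), and when
#'   `observed` is given its empirical quantile (midpoint convention for
#'   ties) and empirical p.
#' @export
random_set_null <- function(matrix, set_size, n_iter, statistic_fn, seed = 17L,
                            observed = NULL) {
  stopifnot(n_iter >= 1L)
  genes <- rownames(matrix)
  if (set_size > length(genes)) stop("set_size exceeds the gene universe")
  z <- zscore_by_gene(matrix)
  vals <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      g <- sample(genes, set_size)
      statistic_fn(activity_score(z, g, zscored = TRUE))
    }, numeric(1))
  })
  out <- list(iterations = n_iter, values = vals,
              summary = list(mean = mean(vals), sd = stats::sd(vals)),
              observed = observed)
  if (!is.null(observed)) {
    out$quantile <- (sum(vals < observed) + 0.5 * sum(vals == observed)) / n_iter
    out$empirical_p <- empirical_p(observed, vals)
  }
  structure(out, class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: %d iterations, mean %.4g, sd %.4g\n",
              x$iterations, x$summary$mean, x$summary$sd))
  if (!is.null(x$observed)) {
    cat(sprintf("  observed %.4g (quantile %.3f, empirical p %.4g)\n",
                x$observed, x$quantile, x$empirical_p))
  }
  invisible(x)
}

#' Polynomial trend fit with R-squared
#'
#' Least-squares polynomial regression of activity on anchor expression using
#' an orthogonal polynomial basis; the trend strength is
#' `R^2 = 1 - SSE / SST` with SST about the mean of `y`.
#'
#' @param x predictor (anchor expression per sample).
#' @param y response (activity per sample).
#' @param degree polynomial degree (default 6).
#' @return list with `fitted`, `r2`, `degree`, and the `lm` fit.
#' @export
poly_fit_r2 <- function(x, y, degree = 6L) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(y) <= degree) stop("need more points than the polynomial degree")
  if (stats::var(y) == 0) stop("zero variance in y: R^2 undefined")
  fit <- stats::lm(y ~ poly(x, degree = degree))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(fitted = stats::fitted(fit), r2 = 1 - sse / sst, degree = degree, fit = fit)
}

#' Recovery-curve gene-set score per cell
#'
#' Rank-based single-cell scoring: genes are ranked by expression in each
#' cell (descending; ties broken randomly under the seed), and the score is
#' the area under the recovery curve of signature genes within the top
#' `ceiling(top_fraction * G)` ranks, normalised by the maximum attainable
#' area. Scores lie in [0, 1] and depend only on within-cell ranks.
#'
#' @param matrix gene x cell `ExpressionMatrix` (counts or log counts).
#' @param signature character vector of gene ids.
#' @param top_fraction fraction of top-ranked genes scanned (default 0.05).
#' @param seed integer seed for random tie-breaking.
#' @return an `ActivityScores` vector over cells.
#' @export
aucell_score <- function(matrix, signature, top_fraction = 0.05, seed = 17L) {
  x <- unclass(matrix)
  genes <- rownames(x)
  sig <- intersect(unique(as.character(signature)), genes)
  if (length(sig) == 0L) stop("no signature gene present in the matrix")
  n_missing <- length(unique(signature)) - length(sig)
  cutoff <- ceiling(top_fraction * nrow(x))
  max_area <- sum(pmin(seq_len(cutoff), length(sig)))
  is_sig <- genes %in% sig
  scores <- with_seed(seed, {
    apply(x, 2L, function(col) {
      ord <- order(col, stats::runif(length(col)), decreasing = TRUE)
      hits <- is_sig[ord][seq_len(cutoff)]
      sum(cumsum(hits)) / max_area
    })
  })
  structure(scores, n_genes_used = length(sig), n_genes_missing = n_missing,
            class = "ActivityScores")
}

#' Rank-sum comparison of score groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test for every pair of groups;
#' exact enumeration when both groups have n <= 8 and no ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param scores numeric (or `ActivityScores`) vector.
#' @param groups group label per score.
#' @return data frame: group1, group2, n1, n2, statistic (W), p.
#' @export
compare_groups <- function(scores, groups) {
  scores <- as.numeric(scores)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need >= 2 groups")
  pairs <- utils::combn(lev, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- scores[groups == pairs[1L, j]]
    b <- scores[groups == pairs[2L, j]]
    exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
    data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
               n1 = length(a), n2 = length(b),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
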