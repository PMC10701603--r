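# Treatment-vs-vehicle differential expression with empirical-Bayes variance
# moderation, unified across log-intensity and count inputs.

#' Moderated-t differential contrast
#'
#' Fits per-gene treated-vs-vehicle means on the log2 scale and moderates the
#' residual variance towards a prior estimated across genes:
#' `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior degrees of
#' freedom `d0` and variance `s0^2` obtained by method-of-moments matching on
#' `log s2` under a scaled-inverse-chi-square model. The moderated t uses
#' `d0 + d` degrees of freedom; p-values are two-sided and BH-adjusted.
#' Count matrices are first transformed to `log2(CPM + 0.5)`.
#'
#' @param matrix an `ExpressionMatrix` (log intensity or counts).
#' @param arm_labels character vector over samples with values `"vehicle"`
#'   and `"treated"` (>= 2 samples each).
#' @return a `ContrastResult` data frame: gene, logFC, t_mod, p, padj,
#'   mean_expr; attributes `d0` and `s0_2` carry the prior.
#' @export
moderated_t_contrast <- function(matrix, arm_labels) {
  x <- unclass(matrix)
  arm_labels <- as.character(arm_labels)
  if (length(arm_labels) != ncol(x)) stop("one arm label per sample required")
  if (!all(arm_labels %in% c("vehicle", "treated"))) {
    stop("arm labels must be 'vehicle' or 'treated'")
  }
  n1 <- sum(arm_labels == "vehicle"); n2 <- sum(arm_labels == "treated")
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per arm")
  if (expr_scale(matrix) == "counts") {
    cpm <- sweep(x, 2L, colSums(x), "/") * 1e6
    x <- log2(cpm + 0.5)
  }
  v <- x[, arm_labels == "vehicle", drop = FALSE]
  t_ <- x[, arm_labels == "treated", drop = FALSE]
  if (all(apply(v, 1L, stats::var) == 0) || all(apply(t_, 1L, stats::var) == 0)) {
    stop("an arm has zero variance for every gene")
  }
  mv <- rowMeans(v); mt <- rowMeans(t_)
  logfc <- mt - mv
  d <- n1 + n2 - 2L
  s2 <- (rowSums((v - mv)^2) + rowSums((t_ - mt)^2)) / d
  eb <- fit_variance_prior(s2, d)
  s2_tilde <- if (is.finite(eb$d0)) {
    (eb$d0 * eb$s0_2 + d * s2) / (eb$d0 + d)
  } else rep(eb$s0_2, length(s2))
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tmod <- ifelse(se > 0, logfc / se, 0)
  df_total <- if (is.finite(eb$d0)) eb$d0 + d else Inf
  p <- 2 * stats::pt(abs(tmod), df = df_total, lower.tail = FALSE)
  res <- data.frame(gene = rownames(x), logFC = logfc, t_mod = tmod, p = p,
                    padj = bh_adjust(p), mean_expr = rowMeans(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- eb$d0
  attr(res, "s0_2") <- eb$s0_2
  class(res) <- c("ContrastResult", class(res))
  res
}

# Method-of-moments fit of the scaled-inverse-chi-square prior on log s^2:
# e_g = log(s2_g) - digamma(d/2) + log(d/2) is unbiased for log sigma2_g;
# excess variance of e over trigamma(d/2) identifies trigamma(d0/2).
fit_variance_prior <- function(s2, d) {
  if (length(s2) < 2L) {
    # single gene: no shrinkage possible; flag d0 = Inf but keep s2 as is
    return(list(d0 = Inf, s0_2 = s2))
  }
  pos <- s2[s2 > 0]
  if (length(pos) < 2L) stop("cannot estimate a variance prior: all variances zero")
  e <- log(pos) - digamma(d / 2) + log(d / 2)
  excess <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    # degenerate moment: complete shrinkage to the common pooled variance
    return(list(d0 = Inf, s0_2 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Select significantly upregulated genes
#'
#' Strict inequalities on both filters: `logFC > logfc_cutoff` and
#' `padj < padj_cutoff`.
#'
#' @param contrast a `ContrastResult`.
#' @param logfc_cutoff log2 fold-change cutoff (default 0.5).
#' @param padj_cutoff adjusted-p cutoff (default 0.05).
#' @return character vector of gene ids.
#' @export
significant_up <- function(contrast, logfc_cutoff = 0.5, padj_cutoff = 0.05) {
  contrast$gene[contrast$logFC > logfc_cutoff & contrast$padj < padj_cutoff]
}
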