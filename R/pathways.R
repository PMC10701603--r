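# Per-sample pathway scoring (ssGSEA-style), correlation with activity with
# family-level aggregation, and hypergeometric overrepresentation analysis.

#' Single-sample gene-set enrichment scores
#'
#' For every sample, genes are ranked ascending by expression and the score
#' is the integrated difference between the weighted in-set ECDF (weights
#' `rank^weight`) and the uniform out-of-set ECDF, walked from the
#' highest-expressed gene down. By convention a set covering every gene
#' scores 0 (the out-of-set ECDF is degenerate). With `normalize = TRUE`
#' scores are min-max normalised across the whole pathway x sample matrix.
#'
#' @param matrix gene x sample `ExpressionMatrix` (>= 2 genes).
#' @param sets a `GeneSetCollection` or named list of gene id vectors.
#' @param weight rank-weighting exponent (default 0.25).
#' @param normalize min-max normalise across the collection (default TRUE).
#' @return a `PathwayScoreMatrix` (pathway x sample); skipped sets (no gene
#'   present) are reported via warning.
#' @export
ssgsea_scores <- function(matrix, sets, weight = 0.25, normalize = TRUE) {
  x <- unclass(matrix)
  if (nrow(x) < 2L) stop("need >= 2 genes")
  genes <- rownames(x)
  keep <- vapply(sets, function(s) any(s %in% genes), logical(1))
  if (any(!keep)) {
    warning(sprintf("%d set(s) with no gene present were skipped", sum(!keep)))
  }
  sets_use <- sets[keep]
  if (length(sets_use) == 0L) stop("no scoreable gene set")
  G <- nrow(x)
  scores <- matrix(0, length(sets_use), ncol(x),
                   dimnames = list(names(sets_use), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")     # ascending rank
    ord <- order(r, decreasing = TRUE)             # walk from top expression
    rw <- r^weight
    for (i in seq_along(sets_use)) {
      in_set <- genes %in% sets_use[[i]]
      n_out <- G - sum(in_set)
      if (n_out == 0L) { scores[i, j] <- 0; next }
      w <- rw[ord] * in_set[ord]
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!in_set[ord]) / n_out
      scores[i, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1L]) / diff(rng)
  }
  structure(scores, method = "ssgsea", weight = weight, normalized = normalize,
            class = c("PathwayScoreMatrix", class(matrix())))
}

#' Correlate pathway scores with activity
#'
#' Pearson correlation of every pathway's score profile with the per-sample
#' activity, plus family-level aggregation (unweighted mean of member
#' correlations) and a display flag marking families with |mean R| above the
#' cutoff.
#'
#' @param pathway_scores pathway x sample matrix (a `PathwayScoreMatrix`).
#' @param activity `ActivityScores` (same samples, matched by name when
#'   named).
#' @param families optional named character vector (pathway -> family).
#' @param display_cutoff absolute family mean R needed for the display flag
#'   (default 0.45).
#' @return a `CorrelationReport`: `pathways` (pathway, r, p) and `families`
#'   (family, n_members, mean_r, display).
#' @export
correlate_with_activity <- function(pathway_scores, activity, families = NULL,
                                    display_cutoff = 0.45) {
  ps <- unclass(pathway_scores)
  act <- as.numeric(activity)
  if (!is.null(names(activity)) && !is.null(colnames(ps))) {
    act <- as.numeric(activity[colnames(ps)])
  }
  if (length(act) != ncol(ps)) stop("activity length does not match samples")
  res <- t(apply(ps, 1L, function(row) {
    if (stats::sd(row) == 0) return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(row, act)
    c(unname(ct$estimate), ct$p.value)
  }))
  pathways <- data.frame(pathway = rownames(ps), r = res[, 1L], p = res[, 2L],
                         row.names = NULL, stringsAsFactors = FALSE)
  fams <- NULL
  if (!is.null(families)) {
    fam_of <- families[pathways$pathway]
    ok <- !is.na(fam_of)
    if (any(ok)) {
      sp <- split(pathways$r[ok], fam_of[ok])
      fams <- data.frame(family = names(sp),
                         n_members = lengths(sp),
                         mean_r = vapply(sp, mean, numeric(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
      fams$display <- abs(fams$mean_r) > display_cutoff
    }
  }
  structure(list(pathways = pathways, families = fams,
                 display_cutoff = display_cutoff),
            class = "CorrelationReport")
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf("CorrelationReport: %d pathways", nrow(x$pathways)))
  if (!is.null(x$families)) {
    cat(sprintf(", %d families (%d flagged at |R| > %.2f)",
                nrow(x$families), sum(x$families$display), x$display_cutoff))
  }
  cat("\n")
  invisible(x)
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test of the signature's overlap with each set:
#' `p = P(X >= k)` with population `|universe|`, successes `|set n universe|`
#' and draws `|signature|`; BH adjustment across sets.
#'
#' @param signature character vector (or `GeneSignature`); must be a subset
#'   of the universe.
#' @param sets `GeneSetCollection` or named list; intersected with the
#'   universe.
#' @param universe character vector of background genes.
#' @return data frame: set, set_size, overlap, expected, p, padj.
#' @export
ora_hypergeom <- function(signature, sets, universe) {
  genes <- if (inherits(signature, "GeneSignature")) signature$genes else unique(as.character(signature))
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe)) stop("signature must be a subset of the universe")
  N <- length(universe); n <- length(genes)
  out <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, expected = n * K / N,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$padj <- bh_adjust(res$p)
  res
}
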