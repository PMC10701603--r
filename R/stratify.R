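# Cohort stratification: panel-gene PCA with activity overlay, k-means
# clustering of panel genes versus activity, classifier extraction, and
# decile cross-tabulation against ordinal annotations.

#' PCA of samples over a gene panel with activity overlay
#'
#' Panel genes are z-scored across samples before the decomposition; the
#' returned coordinates join the per-sample activity (and subtype when a
#' cohort table is supplied).
#'
#' @param matrix gene x sample `ExpressionMatrix`.
#' @param panel character vector of panel gene ids (>= 2 present).
#' @param activity `ActivityScores` over the samples.
#' @param cohort optional `CohortTable` supplying subtype labels.
#' @return list with `samples` (data frame: sample_id, PC1, PC2, activity,
#'   subtype) and `var_explained` (per-component fraction).
#' @export
panel_pca <- function(matrix, panel, activity, cohort = NULL) {
  present <- intersect(unique(panel), rownames(matrix))
  if (length(present) < 2L) stop("need >= 2 panel genes present")
  z <- zscore_by_gene(unclass(matrix)[present, , drop = FALSE])
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  df <- data.frame(sample_id = colnames(matrix),
                   PC1 = pc$x[, 1L],
                   PC2 = if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0,
                   activity = as.numeric(activity[colnames(matrix)]),
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(cohort)) {
    df$subtype <- cohort$subtype[match(df$sample_id, cohort$sample_id)]
  }
  list(samples = df, var_explained = ve, rotation = pc$rotation)
}

#' k-means clustering of panel genes versus activity
#'
#' Lloyd k-means on gene-wise z-scored panel profiles, best of `n_restarts`
#' seeded restarts by total within-cluster sum of squares. Each cluster's
#' correlation with activity is the Pearson R between the cluster's mean
#' z-profile and the per-sample activity; clusters are reported sorted by
#' descending R (and relabelled 1..k in that order). The per-gene average R
#' is reported alongside.
#'
#' @param matrix gene x sample `ExpressionMatrix`.
#' @param panel panel gene ids (`k` < number present).
#' @param activity `ActivityScores` over the samples.
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param n_restarts number of random restarts (default 25).
#' @return a `GeneClustering`: k, `clusters` (gene -> label), `summary`
#'   (cluster, n_genes, r, mean_gene_r), `members` (list), `tot_withinss`.
#' @export
cluster_panel_genes <- function(matrix, panel, activity, k = 4L, seed = 17L,
                                n_restarts = 25L) {
  present <- intersect(unique(panel), rownames(matrix))
  if (k >= length(present)) stop("k must be smaller than the number of panel genes")
  z <- zscore_by_gene(unclass(matrix)[present, , drop = FALSE])
  act <- as.numeric(activity[colnames(matrix)])
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      km <- tryCatch(
        stats::kmeans(z, centers = k, iter.max = 200L, nstart = 1L,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km)) next  # empty cluster or non-convergence: restart
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("all k-means restarts degenerate")
  labels <- best$cluster
  gene_r <- vapply(seq_len(nrow(z)), function(i) {
    if (stats::sd(z[i, ]) == 0) return(NA_real_)
    stats::cor(z[i, ], act)
  }, numeric(1))
  cl_r <- vapply(seq_len(k), function(c) {
    prof <- colMeans(z[labels == c, , drop = FALSE])
    if (stats::sd(prof) == 0) return(NA_real_)
    stats::cor(prof, act)
  }, numeric(1))
  ord <- order(cl_r, decreasing = TRUE)
  relabel <- match(labels, ord)
  names(relabel) <- rownames(z)
  summary <- data.frame(cluster = seq_len(k),
                        n_genes = as.integer(table(factor(relabel, levels = seq_len(k)))),
                        r = cl_r[ord],
                        mean_gene_r = vapply(seq_len(k), function(c) {
                          mean(gene_r[relabel == c], na.rm = TRUE)
                        }, numeric(1)),
                        row.names = NULL)
  members <- split(names(relabel), relabel)
  structure(list(k = k, clusters = relabel, summary = summary,
                 members = members, tot_withinss = best$tot.withinss),
            class = "GeneClustering")
}

#' @export
print.GeneClustering <- function(x, ...) {
  cat(sprintf("GeneClustering: k = %d over %d genes\n", x$k, length(x$clusters)))
  print(x$summary)
  invisible(x)
}

#' Extract the activity-coupled classifier cluster
#'
#' Returns the genes of the cluster with the highest activity correlation,
#' provided that correlation reaches `min_r`; otherwise an empty list with a
#' warning.
#'
#' @param clustering a `GeneClustering`.
#' @param min_r minimum cluster-mean-profile correlation (default 0.5).
#' @return character vector of classifier genes (possibly empty).
#' @export
extract_classifier <- function(clustering, min_r = 0.5) {
  top <- clustering$summary[1L, ]
  if (is.na(top$r) || top$r < min_r) {
    warning(sprintf("no cluster reaches R >= %.2f (best %.3f)", min_r, top$r))
    return(character(0))
  }
  sort(clustering$members[["1"]])
}

#' Decile cross-tabulation of activity against an ordinal annotation
#'
#' Samples are binned into activity deciles (quantile edges, ties to the
#' lower bin) and per-decile category proportions are tabulated; every row
#' sums to 1.
#'
#' @param scores `ActivityScores` (or numeric vector).
#' @param annotation category label per sample (e.g. mitotic low /
#'   intermediate / high).
#' @return matrix (decile x category) of proportions; attribute `n` holds
#'   per-decile counts.
#' @export
decile_crosstab <- function(scores, annotation) {
  s <- as.numeric(scores)
  if (length(s) != length(annotation)) stop("scores and annotation lengths differ")
  edges <- stats::quantile(s, probs = seq(0, 1, 0.1), names = FALSE)
  edges <- unique(edges)
  dec <- cut(s, breaks = edges, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  tab <- table(decile = dec, category = as.character(annotation))
  prop <- prop.table(tab, margin = 1L)
  structure(as.matrix(prop), n = as.integer(rowSums(tab)))
}
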