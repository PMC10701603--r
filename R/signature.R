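# Consensus signature building: model QC, occurrence filtering with elbow
# analysis, anchor-gene correlation filtering.

#' Construct a gene signature
#'
#' @param genes ordered character vector of unique gene ids.
#' @param occurrence named integer vector (gene -> number of models where
#'   upregulated).
#' @param anchor_r named numeric vector (gene -> correlation with the anchor
#'   gene in the reference cohort).
#' @param provenance list of parameters used to build the signature.
#' @return a `GeneSignature`.
#' @export
gene_signature <- function(genes, occurrence = NULL, anchor_r = NULL,
                           provenance = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(genes = genes, occurrence = occurrence, anchor_r = anchor_r,
                 provenance = provenance), class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature: %d genes\n", length(x$genes)))
  if (!is.null(x$provenance$min_models)) {
    cat(sprintf("  min_models %d, models used %s, discarded %s\n",
                x$provenance$min_models,
                x$provenance$n_models_used %||% "?",
                x$provenance$n_models_discarded %||% "?"))
  }
  cat("  ", paste(utils::head(x$genes, 10L), collapse = ", "),
      if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' QC filter on per-model upregulated gene sets
#'
#' A model is discarded when its upregulated-gene count exceeds
#' `median + 3 * MAD` (scaled MAD) across models — the formalisation of
#' dropping models with an unusually high number of upregulated genes.
#'
#' @param model_sets named list of character vectors (per-model up genes).
#' @return list with `retained` (the filtered list) and `report` (data frame:
#'   model, n_up, discarded).
#' @export
qc_filter_models <- function(model_sets) {
  if (length(model_sets) < 3L) stop("need >= 3 model sets for QC")
  counts <- lengths(model_sets)
  cutoff <- stats::median(counts) + 3 * stats::mad(counts)
  discard <- counts > cutoff
  if (all(discard)) stop("QC discarded every model")
  report <- data.frame(model = names(model_sets) %||% seq_along(model_sets),
                       n_up = as.integer(counts), discarded = discard,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = model_sets[!discard], report = report, cutoff = cutoff)
}

#' Occurrence (consensus) filter
#'
#' Counts, for every gene, the number of models in which it was upregulated
#' and retains genes seen in at least `min_models` models.
#'
#' @param model_sets list of character vectors.
#' @param min_models minimum number of models (default 3).
#' @return list with `occurrence` (named integer vector over the union) and
#'   `retained` (character vector).
#' @export
occurrence_filter <- function(model_sets, min_models = 3L) {
  all_genes <- unlist(lapply(model_sets, unique), use.names = FALSE)
  occ <- table(all_genes)
  occurrence <- stats::setNames(as.integer(occ), names(occ))
  list(occurrence = occurrence,
       retained = names(occurrence)[occurrence >= min_models])
}

#' Elbow curve of signature size versus occurrence threshold
#'
#' For each threshold k the curve records how many genes appear in at least
#' k models; the suggested knee maximises the perpendicular distance to the
#' chord joining the first and last curve points. The knee is advisory; the
#' default consensus threshold stays at 3.
#'
#' @param model_sets list of character vectors.
#' @return list with `curve` (data frame: k, size) and `knee` (integer or NA
#'   when the curve is degenerate).
#' @export
elbow_curve <- function(model_sets) {
  occ <- occurrence_filter(model_sets, min_models = 1L)$occurrence
  k_max <- length(model_sets)
  sizes <- vapply(seq_len(k_max), function(k) sum(occ >= k), integer(1))
  curve <- data.frame(k = seq_len(k_max), size = sizes)
  knee <- NA_integer_
  if (k_max >= 3L && sizes[1L] != sizes[k_max]) {
    x1 <- 1; y1 <- sizes[1L]; x2 <- k_max; y2 <- sizes[k_max]
    d <- abs((y2 - y1) * curve$k - (x2 - x1) * curve$size + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    knee <- curve$k[which.max(d)]
  }
  list(curve = curve, knee = knee)
}

#' Anchor-gene correlation filter
#'
#' Retains genes whose expression correlates positively (Pearson R > 0,
#' strict) with the anchor gene across the reference cohort. Genes absent
#' from the reference or with zero variance are dropped with a warning.
#'
#' @param genes candidate gene ids.
#' @param reference gene x sample `ExpressionMatrix` containing the anchor.
#' @param anchor_gene anchor gene id.
#' @param occurrence optional named occurrence counts carried into the
#'   signature.
#' @param provenance optional provenance list to extend.
#' @return a `GeneSignature` of the retained genes with their anchor
#'   correlations.
#' @export
anchor_correlation_filter <- function(genes, reference, anchor_gene,
                                      occurrence = NULL, provenance = list()) {
  if (!anchor_gene %in% rownames(reference)) stop("anchor gene absent from reference")
  anchor <- as.numeric(reference[anchor_gene, ])
  if (stats::sd(anchor) == 0) stop("anchor gene has zero variance")
  genes <- setdiff(unique(as.character(genes)), anchor_gene)
  present <- intersect(genes, rownames(reference))
  if (length(present) < length(genes)) {
    warning(sprintf("%d gene(s) absent from the reference were dropped",
                    length(genes) - length(present)))
  }
  sub <- unclass(reference)[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(sds == 0)))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  r <- if (nrow(sub)) as.numeric(stats::cor(t(sub), anchor)) else numeric(0)
  names(r) <- rownames(sub)
  keep <- names(r)[r > 0]
  prov <- utils::modifyList(provenance, list(anchor_gene = anchor_gene))
  gene_signature(keep,
                 occurrence = if (!is.null(occurrence)) occurrence[keep],
                 anchor_r = r[keep], provenance = prov)
}

#' Build a consensus activity signature
#'
#' End-to-end builder: QC filter on the per-model upregulated sets,
#' occurrence filter at `min_models`, then the anchor-gene correlation
#' filter against the reference cohort.
#'
#' @param model_sets named list of per-model upregulated gene sets.
#' @param reference gene x sample reference `ExpressionMatrix`.
#' @param anchor_gene anchor gene id.
#' @param min_models consensus threshold (default 3).
#' @param qc apply the model QC filter first (default TRUE).
#' @return a `GeneSignature`; provenance records model counts, the QC report
#'   and the elbow curve.
#' @export
build_signature <- function(model_sets, reference, anchor_gene,
                            min_models = 3L, qc = TRUE) {
  n_in <- length(model_sets)
  qc_report <- NULL
  if (qc) {
    q <- qc_filter_models(model_sets)
    model_sets <- q$retained
    qc_report <- q$report
  }
  occ <- occurrence_filter(model_sets, min_models = min_models)
  elbow <- elbow_curve(model_sets)
  prov <- list(min_models = min_models, n_models_used = length(model_sets),
               n_models_discarded = n_in - length(model_sets),
               union_size = length(occ$occurrence), qc_report = qc_report,
               elbow = elbow)
  anchor_correlation_filter(occ$retained, reference, anchor_gene,
                            occurrence = occ$occurrence, provenance = prov)
}

#' Overlap of a signature with other gene sets
#'
#' @param sig a `GeneSignature` or character vector.
#' @param other a `GeneSetCollection` (or named list of gene vectors).
#' @return data frame: set, n_set, intersection, jaccard.
#' @export
signature_overlap <- function(sig, other) {
  genes <- if (inherits(sig, "GeneSignature")) sig$genes else unique(as.character(sig))
  out <- lapply(names(other), function(nm) {
    s <- unique(other[[nm]])
    k <- length(intersect(genes, s))
    u <- length(union(genes, s))
    data.frame(set = nm, n_set = length(s), intersection = k,
               jaccard = if (u > 0) k / u else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
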