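#' @keywords internal
"_PACKAGE"

# Shared domain types. Each constructor validates its invariants; downstream
# functions assume validated instances.

#' Construct an expression matrix
#'
#' A gene x sample numeric matrix carrying a scale tag. Counts must be
#' non-negative; all values must be finite; gene and sample identifiers must
#' be unique.
#'
#' @param values numeric matrix (genes in rows) with rownames and colnames.
#' @param scale one of `"log_intensity"`, `"counts"`, `"log_counts"`.
#' @return an `ExpressionMatrix` (a base matrix with a `scale` attribute).
#' @export
expression_matrix <- function(values, scale = c("log_intensity", "counts", "log_counts")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids (dedupe first)")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (scale == "counts" && any(values < 0)) stop("counts must be non-negative")
  structure(values, scale = scale, class = c("ExpressionMatrix", class(matrix())))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Scale tag of an expression matrix
#' @param x an `ExpressionMatrix`.
#' @return the scale string.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "log_intensity" else s
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids); names unique,
#'   every set non-empty.
#' @param families optional named character vector mapping set name to family.
#' @return a `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, families = NULL) {
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets))) {
    stop("set names must be present and unique")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  if (!is.null(families)) {
    families <- families[intersect(names(families), names(sets))]
  }
  structure(sets, families = families, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Family tags of a gene-set collection
#' @param x a `GeneSetCollection`.
#' @return named character vector (set name -> family), possibly empty.
#' @export
set_families <- function(x) {
  f <- attr(x, "families")
  if (is.null(f)) stats::setNames(character(0), character(0)) else f
}

#' Construct a gene annotation table (TSS coordinates)
#'
#' @param gene_id,chrom,tss,strand vectors of equal length; `tss` is a
#'   0-based base position, one record per gene.
#' @return a `GeneAnnotation` data frame.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = "+") {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   tss = as.integer(tss), strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("one record per gene_id required")
  if (any(df$tss < 0)) stop("tss must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -")
  class(df) <- c("GeneAnnotation", class(df))
  df
}

#' Construct a peak set
#'
#' Intervals are 0-based half-open; sorted by (chrom, start) on construction.
#'
#' @param chrom,start,end interval columns.
#' @return a `PeakSet` data frame.
#' @export
peak_set <- function(chrom = character(0), start = integer(0), end = integer(0)) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    if (any(df$start >= df$end)) stop("peak intervals need start < end")
    if (any(df$start < 0)) stop("peak start must be >= 0")
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("PeakSet", class(df))
  df
}

#' Construct a cohort clinical table
#'
#' @param sample_id,subtype,time,event required columns; `time` in months,
#'   `event` 0/1.
#' @param mitotic_category optional ordinal category (low/intermediate/high).
#' @param extra optional data frame of additional covariates.
#' @param subtype_levels declared subtype vocabulary.
#' @return a `CohortTable` data frame.
#' @export
cohort_table <- function(sample_id, subtype, time, event,
                         mitotic_category = NULL, extra = NULL,
                         subtype_levels = NULL) {
  df <- data.frame(sample_id = as.character(sample_id),
                   subtype = as.character(subtype),
                   time = as.numeric(time), event = as.integer(event),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in cohort table")
  if (any(!is.finite(df$time)) || any(df$time < 0)) stop("survival time must be >= 0")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (is.null(subtype_levels)) subtype_levels <- unique(df$subtype)
  if (!all(df$subtype %in% subtype_levels)) {
    stop("subtype labels outside the declared vocabulary")
  }
  if (!is.null(mitotic_category)) {
    mitotic_category <- as.character(mitotic_category)
    if (!all(mitotic_category %in% c("low", "intermediate", "high"))) {
      stop("mitotic_category must be low/intermediate/high")
    }
    df$mitotic_category <- mitotic_category
  }
  if (!is.null(extra)) df <- cbind(df, extra)
  attr(df, "subtype_levels") <- subtype_levels
  class(df) <- c("CohortTable", class(df))
  df
}
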