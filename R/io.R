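# Readers and writers for the pipeline's external formats: TSV expression
# matrices, GMT gene sets, BED3 peaks, clinical TSV, MatrixMarket triplets.

#' Read a gene x sample expression TSV
#'
#' First column holds gene ids, header row sample ids, body numeric.
#' Duplicate gene ids are collapsed to the row with the highest variance
#' across samples (the count collapsed is reported via a message).
#'
#' @param path TSV file path.
#' @param scale scale tag, see [expression_matrix()].
#' @param transpose if `TRUE` the file is samples-as-rows and is transposed
#'   after reading.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, scale = "log_intensity", transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix: ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad], colnames(body)[j]))
    }
    if (anyNA(col)) {
      stop(sprintf("missing value at row '%s', column '%s'",
                   ids[which(is.na(col))[1L]], colnames(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m <- dedupe_genes(m)
  expression_matrix(m, scale = scale)
}

# Collapse duplicate gene rows, keeping the highest-variance row per gene.
dedupe_genes <- function(m) {
  ids <- rownames(m)
  if (!anyDuplicated(ids)) return(m)
  v <- apply(m, 1L, stats::var)
  keep <- unlist(lapply(split(seq_along(ids), ids), function(idx) {
    idx[which.max(v[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  message(sprintf("collapsed %d duplicate gene row(s) by highest variance",
                  length(ids) - length(keep)))
  m[keep, , drop = FALSE]
}

#' Write an expression matrix as TSV
#' @param x an `ExpressionMatrix` or gene x sample matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: name, description, then genes, tab-separated. A description
#' of the form `family=X` is parsed as the set's family tag. Genes repeated
#' within a line are stored once; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list(); fams <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate set name in GMT: ", nm)
    sets[[nm]] <- unique(f[-(1:2)])
    if (grepl("^family=", f[2L])) fams[nm] <- sub("^family=", "", f[2L])
  }
  gene_set_collection(sets, families = if (length(fams)) fams else NULL)
}

#' Write a gene-set collection as GMT
#' @param x a `GeneSetCollection` or named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  fams <- if (inherits(x, "GeneSetCollection")) set_families(x) else character(0)
  lines <- vapply(names(x), function(nm) {
    desc <- if (nm %in% names(fams)) paste0("family=", fams[[nm]]) else "na"
    paste(c(nm, desc, x[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ peak file
#' @param path BED file path (0-based half-open intervals).
#' @return a `PeakSet`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  peak_set(df[[1L]], df[[2L]], df[[3L]])
}

#' Write a peak set as BED3
#' @param x a `PeakSet`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival TSV into a cohort table
#'
#' Requires columns `sample_id`, `subtype`, `time`, `event`; an optional
#' `mitotic_category` column and any extra columns are carried along.
#'
#' @param path TSV file path.
#' @return a `CohortTable`.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  extra_cols <- setdiff(colnames(df), c(need, "mitotic_category"))
  cohort_table(df$sample_id, df$subtype, df$time, df$event,
               mitotic_category = if ("mitotic_category" %in% colnames(df)) df$mitotic_category,
               extra = if (length(extra_cols)) df[, extra_cols, drop = FALSE])
}

#' Write a cohort table as TSV
#' @param x a `CohortTable`.
#' @param path output path.
#' @export
write_survival_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation TSV
#'
#' Requires columns `gene_id`, `chrom`, `tss` and optionally `strand`
#' (0-based TSS positions).
#'
#' @param path TSV file path.
#' @return a `GeneAnnotation`.
#' @export
read_tss_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("TSS table missing column(s): ", paste(miss, collapse = ", "))
  gene_annotation(df$gene_id, df$chrom, df$tss,
                  strand = if ("strand" %in% colnames(df)) df$strand else "+")
}

#' Write a TSS annotation TSV
#' @param x a `GeneAnnotation`.
#' @param path output path.
#' @export
write_tss_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket expression directory
#'
#' Expects `matrix.mtx` plus `genes.tsv` and `barcodes.tsv` sidecars (one id
#' per line; genes.tsv may have a second symbol column, in which case the
#' first column is used).
#'
#' @param dir directory holding the three files.
#' @param scale scale tag (default counts).
#' @return an `ExpressionMatrix` (dense).
#' @export
read_mtx <- function(dir, scale = "counts") {
  mtx <- file.path(dir, "matrix.mtx")
  gf <- file.path(dir, "genes.tsv"); bf <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) if (!file.exists(f)) stop("missing file: ", f)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  cells <- readLines(bf)
  if (ncol(m) == 0L) stop("MTX with 0 cells")
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop("sidecar lengths do not match matrix dimensions")
  }
  rownames(m) <- genes; colnames(m) <- cells
  m <- dedupe_genes(m)
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as MatrixMarket triplets
#' @param x an `ExpressionMatrix`.
#' @param dir output directory (created if needed).
#' @export
write_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
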