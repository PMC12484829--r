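#' Allele-resolved expression matrix
#'
#' The central container of the package: two gene-by-sample matrices, one per
#' parental allele, sharing identical dimnames, plus an optional matrix of
#' reads that could not be assigned to either allele. The unit of the values
#' (`raw_count`, `tpm` or `cp10m`) and the modality (`cell` for single-cell
#' UMI data, `bulk` for bulk RNA-seq) are carried as metadata and only changed
#' by normalization functions.
#'
#' @param allele1,allele2 Numeric gene-by-sample matrices with identical
#'   dimnames; all values must be non-negative. Conventionally allele1 is the
#'   Mus (reference) allele and allele2 the Cast allele.
#' @param unassigned Optional matrix of allele-unassignable signal with the
#'   same dimnames, or `NULL`.
#' @param unit One of `"raw_count"`, `"tpm"`, `"cp10m"`.
#' @param modality One of `"cell"`, `"bulk"`.
#' @return An object of class `allelic_matrix`.
#' @export
allelic_matrix <- function(allele1, allele2, unassigned = NULL,
                           unit = c("raw_count", "tpm", "cp10m"),
                           modality = c("cell", "bulk")) {
  unit <- match.arg(unit)
  modality <- match.arg(modality)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  if (!identical(dim(allele1), dim(allele2))) {
    stop("allele matrices must have identical dimensions", call. = FALSE)
  }
  if (is.null(rownames(allele1)) || is.null(colnames(allele1))) {
    stop("allele matrices must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (!identical(dimnames(allele1), dimnames(allele2))) {
    stop("allele matrices must share gene and sample names", call. = FALSE)
  }
  if (anyDuplicated(rownames(allele1))) {
    stop("duplicate gene ids in matrix", call. = FALSE)
  }
  if (min(allele1, na.rm = TRUE) < 0 || min(allele2, na.rm = TRUE) < 0) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (!is.null(unassigned)) {
    unassigned <- as.matrix(unassigned)
    if (!identical(dimnames(unassigned), dimnames(allele1))) {
      stop("unassigned matrix must share dimnames with the allele matrices",
           call. = FALSE)
    }
    if (min(unassigned, na.rm = TRUE) < 0) {
      stop("expression values must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(a1 = allele1, a2 = allele2, unassigned = unassigned,
         unit = unit, modality = modality),
    class = "allelic_matrix"
  )
}

#' @export
dim.allelic_matrix <- function(x) dim(x$a1)

#' Gene and sample identifiers of an allelic matrix
#' @param m An `allelic_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$a1)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$a1)

#' @export
print.allelic_matrix <- function(x, ...) {
  cat(sprintf(
    "<allelic_matrix> %d genes x %d samples [%s, %s]%s\n",
    nrow(x$a1), ncol(x$a1), x$unit, x$modality,
    if (is.null(x$unassigned)) "" else " + unassigned"
  ))
  invisible(x)
}

#' Subset an allelic matrix by genes and/or samples
#'
#' @param x An `allelic_matrix`.
#' @param genes,samples Character vectors of ids (or logical/integer indices);
#'   `NULL` keeps everything.
#' @return An `allelic_matrix`.
#' @export
subset_allelic <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$a1)) else genes
  si <- if (is.null(samples)) seq_len(ncol(x$a1)) else samples
  allelic_matrix(
    x$a1[gi, si, drop = FALSE],
    x$a2[gi, si, drop = FALSE],
    unassigned = if (is.null(x$unassigned)) NULL else
      x$unassigned[gi, si, drop = FALSE],
    unit = x$unit, modality = x$modality
  )
}

#' Total (both-allele) expression matrix
#'
#' @param m An `allelic_matrix`.
#' @param include_unassigned Add the unassigned matrix to the total when
#'   present. Default `FALSE`: allelic statistics exclude unassignable signal.
#' @return A numeric gene-by-sample matrix.
#' @export
total_expression <- function(m, include_unassigned = FALSE) {
  tot <- m$a1 + m$a2
  if (include_unassigned && !is.null(m$unassigned)) tot <- tot + m$unassigned
  tot
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.allelic_matrix <- function(x, ...) {
  long <- function(mat, allele) {
    tibble::tibble(
      gene_id = rep(rownames(mat), times = ncol(mat)),
      sample_id = rep(colnames(mat), each = nrow(mat)),
      allele = allele,
      value = as.vector(mat)
    )
  }
  out <- dplyr::bind_rows(long(x$a1, "a1"), long(x$a2, "a2"))
  if (!is.null(x$unassigned)) out <- dplyr::bind_rows(out, long(x$unassigned, "unassigned"))
  out$unit <- x$unit
  out
}

# ---- reading / writing ------------------------------------------------------

read_matrix_tsv <- function(path) {
  # base strtod parsing is correctly rounded, so %.17g output round-trips
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"gene_id" %in% names(df)) {
    stop(sprintf("matrix file '%s' lacks a gene_id column", path), call. = FALSE)
  }
  vals <- df[setdiff(names(df), "gene_id")]
  m <- vapply(vals, as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(vals)))
  rownames(m) <- df$gene_id
  m
}

read_matrix_mtx <- function(path) {
  genes <- readLines(paste0(path, ".rownames"))
  samples <- readLines(paste0(path, ".colnames"))
  m <- as.matrix(Matrix::readMM(path))
  dimnames(m) <- list(genes, samples)
  m
}

#' Read a pair of allele-split count matrices
#'
#' Reads one matrix per allele and aligns them on the intersection of their
#' gene and sample universes. TSV matrices carry genes as rows (a `gene_id`
#' column) and a header row of sample ids; MatrixMarket triplets expect
#' `<path>.rownames` / `<path>.colnames` sidecar files.
#'
#' @param path_allele1,path_allele2 Paths to the two matrices.
#' @param format `"tsv"` or `"mtx"`.
#' @param unassigned_path Optional path to an unassigned-read matrix.
#' @param modality `"cell"` or `"bulk"`.
#' @return An `allelic_matrix` with `unit = "raw_count"`.
#' @export
read_allelic_counts <- function(path_allele1, path_allele2,
                                format = c("tsv", "mtx"),
                                unassigned_path = NULL,
                                modality = c("cell", "bulk")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  reader <- switch(format, tsv = read_matrix_tsv, mtx = read_matrix_mtx)
  m1 <- reader(path_allele1)
  m2 <- reader(path_allele2)
  for (m in list(m1, m2)) {
    if (any(m < 0)) stop("negative count encountered", call. = FALSE)
  }
  genes <- intersect(rownames(m1), rownames(m2))
  samples <- intersect(colnames(m1), colnames(m2))
  if (length(samples) == 0L) {
    stop("allele matrices share no samples", call. = FALSE)
  }
  if (length(genes) == 0L) {
    stop("allele matrices share no genes", call. = FALSE)
  }
  ua <- NULL
  if (!is.null(unassigned_path)) {
    ua <- reader(unassigned_path)
    genes <- intersect(genes, rownames(ua))
    samples <- intersect(samples, colnames(ua))
    ua <- ua[genes, samples, drop = FALSE]
  }
  allelic_matrix(m1[genes, samples, drop = FALSE],
                 m2[genes, samples, drop = FALSE],
                 unassigned = ua, unit = "raw_count", modality = modality)
}

write_matrix_tsv <- function(m, path) {
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Write an allelic matrix as a pair of TSV files
#'
#' Values are written in full decimal precision so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param m An `allelic_matrix`.
#' @param path_allele1,path_allele2 Output paths.
#' @param unassigned_path Optional output path for the unassigned matrix.
#' @return Invisibly, `m`.
#' @export
write_allelic_counts <- function(m, path_allele1, path_allele2,
                                 unassigned_path = NULL) {
  write_matrix_tsv(m$a1, path_allele1)
  write_matrix_tsv(m$a2, path_allele2)
  if (!is.null(unassigned_path) && !is.null(m$unassigned)) {
    write_matrix_tsv(m$unassigned, unassigned_path)
  }
  invisible(m)
}
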