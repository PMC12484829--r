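#' Read gene annotation from BED or GFF3
#'
#' Internal coordinates are 0-based half-open (BED convention); GFF3 records
#' (1-based inclusive) are converted at this boundary. The transcription start
#' site (TSS) is the 5' end of the gene (`start` on `+`, `end` on `-`) and the
#' TES the 3' end. Gene length is the exonic length when the source provides
#' one (GFF3 `exonic_length` attribute), otherwise the genomic span.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`, `length`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (format == "bed") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 6L)
    if (length(bad)) {
      stop(sprintf("malformed BED line %d: need 6 columns (strand required)", bad[1]),
           call. = FALSE)
    }
    ann <- tibble::tibble(
      chrom = vapply(fields, `[[`, "", 1L),
      start = as.numeric(vapply(fields, `[[`, "", 2L)),
      end = as.numeric(vapply(fields, `[[`, "", 3L)),
      gene_id = vapply(fields, `[[`, "", 4L),
      strand = vapply(fields, `[[`, "", 6L)
    )
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 1L) < 9L)
    if (length(bad)) {
      stop(sprintf("malformed GFF3 line %d: need 9 columns", bad[1]), call. = FALSE)
    }
    keep <- vapply(fields, `[[`, "", 3L) == "gene"
    fields <- fields[keep]
    attr_field <- vapply(fields, `[[`, "", 9L)
    get_attr <- function(attrs, key) {
      m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))
      m[, 2]
    }
    ids <- get_attr(attr_field, "ID")
    if (anyNA(ids)) {
      stop("GFF3 gene record without ID attribute", call. = FALSE)
    }
    ann <- tibble::tibble(
      chrom = vapply(fields, `[[`, "", 1L),
      # 1-based inclusive -> 0-based half-open
      start = as.numeric(vapply(fields, `[[`, "", 4L)) - 1,
      end = as.numeric(vapply(fields, `[[`, "", 5L)),
      gene_id = ids,
      strand = vapply(fields, `[[`, "", 7L),
      exonic_length = suppressWarnings(as.numeric(get_attr(attr_field, "exonic_length")))
    )
  }
  if (any(is.na(ann$start) | is.na(ann$end))) {
    stop("malformed coordinates in annotation", call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("missing or invalid strand in annotation", call. = FALSE)
  }
  if (any(ann$start >= ann$end)) {
    stop("gene with start >= end in annotation", call. = FALSE)
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene ids in annotation: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  ann <- dplyr::mutate(
    ann,
    tss = ifelse(.data$strand == "+", .data$start, .data$end),
    tes = ifelse(.data$strand == "+", .data$end, .data$start),
    length = if ("exonic_length" %in% names(ann)) {
      ifelse(is.na(.data$exonic_length), .data$end - .data$start, .data$exonic_length)
    } else {
      .data$end - .data$start
    }
  )
  dplyr::select(ann, "gene_id", "chrom", "start", "end", "strand",
                "tss", "tes", "length")
}

#' Write gene annotation back to GFF3
#'
#' The inverse of [read_gene_annotation()] for the GFF3 dialect: internal
#' 0-based half-open spans are converted back to 1-based inclusive
#' coordinates, so read -> write -> read is the identity.
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @export
write_gene_annotation_gff3 <- function(annotation, path) {
  lines <- sprintf(
    "%s\tallelicomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    annotation$chrom, annotation$start + 1, annotation$end,
    annotation$strand, annotation$gene_id
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(annotation)
}

#' Write gene annotation as BED6
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @export
write_gene_annotation_bed <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   annotation$chrom, annotation$start, annotation$end,
                   annotation$gene_id, annotation$strand)
  writeLines(lines, path)
  invisible(annotation)
}

#' Read a per-allele copy-number profile
#'
#' BED-like table with columns chrom, start, end, copies_allele1,
#' copies_allele2 (whitespace separated, no header). Coordinates are 0-based
#' half-open. Genes outside any interval carry one copy per allele.
#'
#' @param path Path to the profile file.
#' @param profile_id Identifier stored on the result (defaults to file name).
#' @return A `copy_profile`: tibble of intervals with attribute `profile_id`.
#' @export
read_copy_profile <- function(path, profile_id = NULL) {
  df <- utils::read.table(path, header = FALSE, col.names = c(
    "chrom", "start", "end", "copies_allele1", "copies_allele2"
  ), colClasses = c("character", "numeric", "numeric", "integer", "integer"))
  copy_profile(tibble::as_tibble(df),
               profile_id = profile_id %||% basename(path))
}

#' Construct a copy-number profile
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`,
#'   `copies_allele1`, `copies_allele2` (copies in \{0, 1\}).
#' @param profile_id Identifier string.
#' @return A `copy_profile` object.
#' @export
copy_profile <- function(intervals, profile_id = "profile") {
  required <- c("chrom", "start", "end", "copies_allele1", "copies_allele2")
  if (!all(required %in% names(intervals))) {
    stop("copy profile needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!all(unlist(intervals[c("copies_allele1", "copies_allele2")]) %in% 0:1)) {
    stop("per-allele copies must be 0 or 1", call. = FALSE)
  }
  if (any(intervals$start >= intervals$end)) {
    stop("copy interval with start >= end", call. = FALSE)
  }
  by_chrom <- split(intervals, intervals$chrom)
  for (iv in by_chrom) {
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      stop(sprintf("overlapping copy intervals on %s", iv$chrom[1]),
           call. = FALSE)
    }
  }
  structure(tibble::as_tibble(intervals), profile_id = profile_id,
            class = c("copy_profile", class(tibble::tibble())))
}

#' Read named genomic regions (BED-like)
#'
#' Columns chrom, start, end, name; 0-based half-open.
#'
#' @param path Path to the regions file.
#' @return Tibble with columns `name`, `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  if (any(df$start >= df$end)) stop("region with start >= end", call. = FALSE)
  tibble::as_tibble(df)[, c("name", "chrom", "start", "end")]
}

#' Per-gene copy numbers under a profile
#'
#' Resolves each gene to its per-allele copy number by overlap of the gene
#' span with the profile intervals; a gene overlapping two intervals with
#' conflicting copies is an error.
#'
#' @param annotation Annotation tibble.
#' @param profile A `copy_profile`.
#' @return Tibble with `gene_id`, `copies_allele1`, `copies_allele2`,
#'   `copies_total`.
#' @export
gene_copy_numbers <- function(annotation, profile) {
  c1 <- rep(1L, nrow(annotation))
  c2 <- rep(1L, nrow(annotation))
  hit <- rep(FALSE, nrow(annotation))
  for (i in seq_len(nrow(profile))) {
    ov <- annotation$chrom == profile$chrom[i] &
      annotation$start < profile$end[i] &
      annotation$end > profile$start[i]
    conflict <- ov & hit &
      (c1 != profile$copies_allele1[i] | c2 != profile$copies_allele2[i])
    if (any(conflict)) {
      stop(sprintf(
        "gene(s) overlap copy intervals with conflicting copies: %s",
        paste(utils::head(annotation$gene_id[conflict], 5), collapse = ", ")
      ), call. = FALSE)
    }
    c1[ov] <- profile$copies_allele1[i]
    c2[ov] <- profile$copies_allele2[i]
    hit <- hit | ov
  }
  tibble::tibble(gene_id = annotation$gene_id,
                 copies_allele1 = c1, copies_allele2 = c2,
                 copies_total = c1 + c2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
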