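#' Stepwise-constant coverage track
#'
#' Per-chromosome sorted, non-overlapping intervals with a value; uncovered
#' bases read as zero (the missing-data-as-zero convention of coverage
#' tooling).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, `value`.
#' @param allele Optional allele label.
#' @param normalization `"raw"` or `"cp10m"`.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(intervals, allele = NA_character_,
                           normalization = c("raw", "cp10m")) {
  normalization <- match.arg(normalization)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    stop("zero- or negative-length coverage interval", call. = FALSE)
  }
  by_chrom <- split(intervals, intervals$chrom)
  chroms <- purrr::map(by_chrom, function(iv) {
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      stop(sprintf("overlapping coverage intervals on %s", iv$chrom[1]),
           call. = FALSE)
    }
    # cumulative integral at interval ends enables O(log n) region sums
    iv$cum <- cumsum(iv$value * (iv$end - iv$start))
    iv
  })
  structure(list(chroms = chroms, allele = allele,
                 normalization = normalization),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, nrow, 1L))
  cat(sprintf("<coverage_track> %d intervals on %d chromosome(s) [%s]\n",
              n, length(x$chroms), x$normalization))
  invisible(x)
}

#' Read a 4-column bedGraph file into a coverage track
#'
#' @param path Path to the bedGraph (chrom, start, end, value; 0-based
#'   half-open).
#' @param allele Optional allele label.
#' @return A `coverage_track` with `normalization = "raw"`.
#' @export
read_coverage <- function(path, allele = NA_character_) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  coverage_track(tibble::as_tibble(df), allele = allele)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  df <- dplyr::bind_rows(purrr::map(track$chroms,
                                    ~ .x[c("chrom", "start", "end", "value")]))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(track)
}

#' Scale a raw track to counts per ten million (CP10M)
#'
#' @param track A raw `coverage_track`.
#' @param total_count Total read count of the library.
#' @return The scaled `coverage_track` (`normalization = "cp10m"`).
#' @export
cp10m_scale <- function(track, total_count) {
  if (track$normalization != "raw") {
    stop("track is already normalized (", track$normalization, ")",
         call. = FALSE)
  }
  if (total_count <= 0) stop("total_count must be positive", call. = FALSE)
  f <- 1e7 / total_count
  track$chroms <- purrr::map(track$chroms, function(iv) {
    iv$value <- iv$value * f
    iv$cum <- iv$cum * f
    iv
  })
  track$normalization <- "cp10m"
  track
}

# integral of the track over [a, b) on one chromosome (missing = 0)
track_integral <- function(iv, a, b) {
  if (is.null(iv) || nrow(iv) == 0 || b <= a) return(0)
  # clip query to intervals overlapping [a, b)
  i1 <- findInterval(a, iv$start)
  lo <- max(1L, i1)
  hi <- findInterval(b - 1e-9, iv$start)
  if (hi < 1) return(0)
  total <- 0
  for (i in max(1L, lo):hi) {
    s <- max(iv$start[i], a)
    e <- min(iv$end[i], b)
    if (e > s) total <- total + iv$value[i] * (e - s)
  }
  total
}

#' Promoter region of genes
#'
#' The 1 kb (by default) biologically upstream of the TSS: genomically left
#' of the TSS on `+` genes, right of it on `-` genes; clipped at chromosome
#' bounds when lengths are supplied.
#'
#' @param genes Annotation tibble (one or more genes).
#' @param upstream Promoter size in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Tibble with `name`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_region <- function(genes, upstream = 1000, chrom_lengths = NULL) {
  start <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss)
  end <- ifelse(genes$strand == "+", genes$tss, genes$tss + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  tibble::tibble(name = genes$gene_id, chrom = genes$chrom,
                 start = start, end = end, strand = genes$strand)
}

#' Gene-body region (TSS to TES)
#'
#' @param genes Annotation tibble.
#' @return Tibble with `name`, `chrom`, `start`, `end`, `strand`.
#' @export
body_region <- function(genes) {
  tibble::tibble(name = genes$gene_id, chrom = genes$chrom,
                 start = pmin(genes$tss, genes$tes),
                 end = pmax(genes$tss, genes$tes),
                 strand = genes$strand)
}

#' Base-weighted mean signal over regions
#'
#' @param track A `coverage_track`.
#' @param regions Tibble with `name`, `chrom`, `start`, `end`.
#' @return Tibble with `name`, `mean_signal`.
#' @export
region_mean_signal <- function(track, regions) {
  if (any(regions$end <= regions$start)) {
    stop("zero-length region", call. = FALSE)
  }
  means <- vapply(seq_len(nrow(regions)), function(i) {
    iv <- track$chroms[[regions$chrom[i]]]
    track_integral(iv, regions$start[i], regions$end[i]) /
      (regions$end[i] - regions$start[i])
  }, numeric(1))
  tibble::tibble(name = regions$name, mean_signal = means)
}

#' Scale-regions metaprofile over a gene set
#'
#' Flanks are binned natively (`bin` bp per bin); the gene body is rescaled
#' to `body` bp by evaluating the base-weighted mean over `body / bin` equal
#' fractions of the actual body (linear rescaling of the stepwise signal).
#' Minus-strand genes are orientation-flipped so every profile runs 5' to
#' 3'. Genes with a body shorter than one bin are skipped with a warning.
#'
#' @param track A `coverage_track`.
#' @param genes Annotation tibble.
#' @param bin Bin size (bp).
#' @param body Body target length (bp).
#' @param flank Upstream/downstream flank length (bp).
#' @return A `metaprofile` tibble: `bin` (1-based index), `segment`
#'   (upstream/body/downstream), `mean`, `se`, `n_genes`.
#' @export
metaprofile <- function(track, genes, bin = 100, body = 3000, flank = 1500) {
  if (nrow(genes) == 0) stop("empty gene set", call. = FALSE)
  n_flank <- flank / bin
  n_body <- body / bin
  n_bins <- as.integer(2 * n_flank + n_body)
  profs <- list()
  skipped <- 0
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    blen <- abs(g$tes - g$tss)
    if (blen < bin) {
      skipped <- skipped + 1
      next
    }
    iv <- track$chroms[[g$chrom]]
    fwd <- g$strand == "+"
    gstart <- min(g$tss, g$tes)
    gend <- max(g$tss, g$tes)
    up_edges <- if (fwd) seq(g$tss - flank, g$tss, by = bin) else
      rev(seq(g$tss, g$tss + flank, by = bin))
    down_edges <- if (fwd) seq(g$tes, g$tes + flank, by = bin) else
      rev(seq(g$tes - flank, g$tes, by = bin))
    body_edges <- if (fwd) seq(gstart, gend, length.out = n_body + 1) else
      rev(seq(gstart, gend, length.out = n_body + 1))
    bin_means <- function(edges) {
      vapply(seq_len(length(edges) - 1), function(j) {
        a <- min(edges[j], edges[j + 1])
        b <- max(edges[j], edges[j + 1])
        track_integral(iv, a, b) / (b - a)
      }, numeric(1))
    }
    profs[[length(profs) + 1L]] <-
      c(bin_means(up_edges), bin_means(body_edges), bin_means(down_edges))
  }
  if (skipped > 0) {
    warning(skipped, " gene(s) shorter than one bin skipped")
  }
  if (length(profs) == 0) stop("no usable genes", call. = FALSE)
  pm <- do.call(rbind, profs)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    segment = rep(c("upstream", "body", "downstream"),
                  times = c(n_flank, n_body, n_flank)),
    mean = colMeans(pm),
    se = apply(pm, 2, stats::sd) / sqrt(nrow(pm)),
    n_genes = nrow(pm)
  )
  structure(out, bin_size = bin, body = body, flank = flank,
            class = c("metaprofile", class(out)))
}

# shared engine for the family-wise paired/two-sample comparisons: `pairs`
# is a named list of list(x, y); returns p and BH-adjusted p per element
family_tests <- function(pairs, paired, correction = "bh",
                         var_equal = TRUE) {
  rows <- purrr::imap_dfr(pairs, function(pr, nm) {
    if (paired && length(pr$x) != length(pr$y)) {
      stop("misaligned pairing in '", nm, "'", call. = FALSE)
    }
    tt <- safe_t_test(pr$x, pr$y, paired = paired, var.equal = var_equal)
    tibble::tibble(name = nm, estimate = tt$estimate, p_value = tt$p.value)
  })
  rows$p_adj <- adjust_pvalues(rows$p_value, correction)
  rows
}

#' Paired comparison of region signal between two timepoints
#'
#' Two-sided paired t-tests over per-gene region means, gene-matched between
#' timepoints. Pass plain numeric vectors for a single test, or named lists
#' of vectors (one element per mark or gene set analysed together) to
#' correct across the family with Benjamini-Hochberg.
#'
#' @param values_t0,values_t24 Numeric vectors (aligned by gene) or named
#'   lists of such vectors.
#' @param correction `"bh"` or `"bonferroni"`.
#' @return Tibble with `name`, `estimate` (mean difference t24 - t0),
#'   `p_value`, `p_adj`.
#' @export
compare_timepoints <- function(values_t0, values_t24, correction = "bh") {
  if (!is.list(values_t0)) {
    values_t0 <- list(track = values_t0)
    values_t24 <- list(track = values_t24)
  }
  pairs <- purrr::map2(values_t24, values_t0, ~ list(x = .x, y = .y))
  family_tests(pairs, paired = TRUE, correction = correction)
}

#' Compare region signal between upregulated and non-upregulated gene sets
#'
#' Two-sided two-sample Student t-tests (independent gene sets); the same
#' family-wise interface as [compare_timepoints()].
#'
#' @param up_values,non_up_values Numeric vectors or named lists of vectors.
#' @param correction `"bh"` or `"bonferroni"`.
#' @return Tibble with `name`, `estimate` (mean up - mean non-up),
#'   `p_value`, `p_adj`.
#' @export
compare_gene_sets <- function(up_values, non_up_values, correction = "bh") {
  if (!is.list(up_values)) {
    up_values <- list(contrast = up_values)
    non_up_values <- list(contrast = non_up_values)
  }
  pairs <- purrr::map2(up_values, non_up_values, ~ list(x = .x, y = .y))
  family_tests(pairs, paired = FALSE, correction = correction,
               var_equal = TRUE)
}
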