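#' Simulation configuration
#'
#' Parameters of the synthetic allelic-expression generator. The generator
#' emulates the downstream shape of allele-split UMI/read count matrices from
#' hybrid (Mus x Cast) mouse pluripotent stem cells: negative-binomial counts
#' per gene, allele and cell around log-normal per-gene base means, genotypes
#' with X monosomy or heterozygous segmental deletions encoded as per-allele
#' copy-number profiles, a slight mapping bias towards the reference (Mus)
#' allele, and dosage compensation modeled as a mean-level upregulation factor
#' `u` applied to the remaining expressed allele of a compensated gene
#' wherever that gene is monoallelically expressed.
#'
#' @param seed Integer seed fixing every draw.
#' @param chrom_plan Tibble with columns `chrom`, `length`, `n_genes`. The
#'   default places 400 genes on a 171 Mb X chromosome and 7600 genes on
#'   three autosomes, so X-linked genes make up ~5% of the transcriptome as
#'   in real mouse data.
#' @param genotypes Tibble with columns `label`, `n`, `profile` (name of an
#'   entry of `profiles`), and optionally `dox` (logical; cis-silencing
#'   induced). Default: 60 biallelic XX samples and 40 X^Cast^O^Mus samples.
#' @param profiles Named list of `copy_profile` objects. Defaults to the
#'   standard XX / XCastOMus / XMusOCast / XY monosomy profiles on `x_chrom`.
#' @param x_chrom Name of the X chromosome in `chrom_plan`.
#' @param base_mean_log_mu,base_mean_log_sigma Log-normal (natural log)
#'   parameters of the per-gene per-allele base expression level.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); 0.3 is typical of single-cell UMI counts,
#'   0.05 of bulk libraries.
#' @param library_size_mean Expected total counts per sample over genes and
#'   both alleles.
#' @param library_size_cv Coefficient of variation of per-sample depth.
#' @param pi_u Fraction of genes designated dosage-compensated.
#' @param u Upregulation factor on the remaining active allele of a
#'   compensated, monoallelically expressed gene.
#' @param mapping_bias_b Multiplicative factor on allele-1 (Mus) means,
#'   mirroring the slight reference-mapping bias of hybrid alignments.
#' @param pi_protein_only Fraction of non-RNA-compensated genes compensated
#'   at the protein level only.
#' @param protein_noise_sigma SD of log2 protein abundance across replicates
#'   (0.3 is roughly a 23% CV, typical of DIA label-free quantification).
#' @param silencing Optional cis-silencing experiment: a list with `chrom`,
#'   `start`, `end`, `allele` (1 or 2); genes whose TSS falls in the interval
#'   are silenced on that allele in `dox = TRUE` genotypes.
#' @param silencing_efficiency Residual expression fraction on a silenced
#'   allele.
#' @param modality `"cell"` or `"bulk"` (sets the dispersion/depth defaults).
#' @param markers Rename three highly expressed autosomal genes to the
#'   pluripotency markers Esrrb, Nanog, Pou5f1 so marker-based QC can run.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_plan = default_chrom_plan(),
                              genotypes = default_genotypes(),
                              profiles = NULL,
                              x_chrom = "chrX",
                              base_mean_log_mu = 2,
                              base_mean_log_sigma = 1,
                              nb_dispersion = NULL,
                              library_size_mean = NULL,
                              library_size_cv = 0.2,
                              pi_u = 0.4,
                              u = 2,
                              mapping_bias_b = 1.05,
                              pi_protein_only = 0.35,
                              protein_noise_sigma = 0.3,
                              silencing = NULL,
                              silencing_efficiency = 0.1,
                              modality = c("cell", "bulk"),
                              markers = TRUE) {
  modality <- match.arg(modality)
  if (is.null(nb_dispersion)) {
    nb_dispersion <- if (modality == "cell") 0.3 else 0.05
  }
  if (is.null(library_size_mean)) {
    library_size_mean <- if (modality == "cell") 4e5 else 5e6
  }
  stopifnot(pi_u >= 0, pi_u <= 1, pi_protein_only >= 0, pi_protein_only <= 1,
            u >= 1, nb_dispersion >= 0, library_size_cv >= 0)
  if (is.null(profiles)) {
    xlen <- chrom_plan$length[chrom_plan$chrom == x_chrom]
    # plans without an X chromosome still get the standard profiles; their
    # intervals then simply cover no genes
    if (length(xlen) != 1) xlen <- 171e6
    profiles <- standard_copy_profiles(x_chrom, xlen)
  }
  missing_prof <- setdiff(genotypes$profile, names(profiles))
  if (length(missing_prof)) {
    stop("genotype references unknown copy profile: ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  if (!"dox" %in% names(genotypes)) genotypes$dox <- FALSE
  structure(list(
    seed = as.integer(seed), chrom_plan = chrom_plan, genotypes = genotypes,
    profiles = profiles, x_chrom = x_chrom,
    base_mean_log_mu = base_mean_log_mu,
    base_mean_log_sigma = base_mean_log_sigma,
    nb_dispersion = nb_dispersion, library_size_mean = library_size_mean,
    library_size_cv = library_size_cv, pi_u = pi_u, u = u,
    mapping_bias_b = mapping_bias_b, pi_protein_only = pi_protein_only,
    protein_noise_sigma = protein_noise_sigma, silencing = silencing,
    silencing_efficiency = silencing_efficiency, modality = modality,
    markers = markers
  ), class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_chrom_plan <- function() {
  tibble::tibble(
    chrom = c("chrX", "chr1", "chr2", "chr3"),
    length = c(171e6, 195e6, 182e6, 160e6),
    n_genes = c(400L, 2600L, 2600L, 2400L)
  )
}

#' @rdname simulation_config
#' @export
default_genotypes <- function() {
  tibble::tibble(label = c("XX", "XCastOMus"),
                 n = c(60L, 40L),
                 profile = c("XX", "XCastOMus"),
                 dox = FALSE)
}

#' Standard X-monosomy copy profiles
#'
#' Allele 1 is the Mus allele, allele 2 the Cast allele. `XCastOMus` has lost
#' the Mus X (allele-1 copies 0 on the X), `XMusOCast` and `XY` the Cast X.
#'
#' @param x_chrom X chromosome name.
#' @param x_length X chromosome length in bp.
#' @return Named list of `copy_profile` objects.
#' @export
standard_copy_profiles <- function(x_chrom = "chrX", x_length = 171e6) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), copies_allele1 = integer(),
                          copies_allele2 = integer())
  xiv <- function(c1, c2) tibble::tibble(
    chrom = x_chrom, start = 0, end = x_length,
    copies_allele1 = c1, copies_allele2 = c2
  )
  list(
    XX = copy_profile(empty, "XX"),
    XCastOMus = copy_profile(xiv(0L, 1L), "XCastOMus"),
    XMusOCast = copy_profile(xiv(1L, 0L), "XMusOCast"),
    XY = copy_profile(xiv(1L, 0L), "XY")
  )
}

#' Simulate a gene annotation
#'
#' Genes are placed without overlap by partitioning each chromosome into
#' equal slots, one gene per slot, with random position within the slot and
#' random strand; fully deterministic under the config seed.
#'
#' @param config A `simulation_config`.
#' @return Annotation tibble as from [read_gene_annotation()].
#' @export
simulate_annotation <- function(config) {
  plan <- config$chrom_plan
  if (nrow(plan) == 0) stop("empty chrom_plan", call. = FALSE)
  withr::with_seed(config$seed, {
    out <- purrr::pmap_dfr(plan, function(chrom, length, n_genes) {
      if (n_genes == 0L) return(tibble::tibble())
      slot <- length / n_genes
      if (slot < 2000) {
        stop(sprintf("n_genes too large for %s (slot %.0f bp)", chrom, slot),
             call. = FALSE)
      }
      glen <- round(stats::runif(n_genes, 2000, min(20000, slot * 0.5)))
      start <- round((seq_len(n_genes) - 1) * slot +
                       stats::runif(n_genes, 0, 1) * (slot - glen))
      tibble::tibble(
        gene_id = sprintf("%s_g%04d", chrom, seq_len(n_genes)),
        chrom = chrom, start = start, end = start + glen,
        strand = sample(c("+", "-"), n_genes, replace = TRUE)
      )
    })
    if (nrow(out) == 0) {
      return(tibble::tibble(gene_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            strand = character(), tss = numeric(),
                            tes = numeric(), length = numeric()))
    }
    if (isTRUE(config$markers)) {
      auto <- which(out$chrom != config$x_chrom)
      if (length(auto) >= 3) {
        out$gene_id[auto[1:3]] <- c("Esrrb", "Nanog", "Pou5f1")
      }
    }
    dplyr::mutate(
      out,
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start),
      length = .data$end - .data$start
    )
  })
}

# Expected per-allele mean (relative units, before library scaling) for one
# genotype. Encodes copy number, mapping bias, cis silencing and the
# compensation factor u on the remaining expressed allele.
genotype_expected_means <- function(annotation, base_mean, compensated,
                                    profile, config, dox = FALSE) {
  cn <- gene_copy_numbers(annotation, profile)
  mu1 <- base_mean * cn$copies_allele1 * config$mapping_bias_b
  mu2 <- base_mean * cn$copies_allele2
  sil <- rep(FALSE, nrow(annotation))
  if (dox && !is.null(config$silencing)) {
    s <- config$silencing
    sil <- annotation$chrom == s$chrom & annotation$tss >= s$start &
      annotation$tss < s$end
    if (s$allele == 1) mu1[sil] <- mu1[sil] * config$silencing_efficiency
    else mu2[sil] <- mu2[sil] * config$silencing_efficiency
  }
  # a gene is monoallelically expressed when the other allele is deleted or
  # cis-silenced; compensated genes then get u on the expressed allele
  up1 <- compensated & (cn$copies_allele2 == 0 |
                          (sil & (config$silencing %||% list(allele = 0))$allele == 2)) &
    cn$copies_allele1 > 0
  up2 <- compensated & (cn$copies_allele1 == 0 |
                          (sil & (config$silencing %||% list(allele = 0))$allele == 1)) &
    cn$copies_allele2 > 0
  mu1[up1] <- mu1[up1] * config$u
  mu2[up2] <- mu2[up2] * config$u
  list(mu1 = mu1, mu2 = mu2, silenced = sil,
       deleted_a1 = cn$copies_allele1 == 0, deleted_a2 = cn$copies_allele2 == 0)
}

nb_draw <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate allele-resolved counts with ground truth
#'
#' Draws negative-binomial allelic counts for every genotype in the config.
#' The per-cell expected depth is identical across genotypes (sequencing
#' depth does not depend on karyotype); monosomy therefore shows up as a
#' redistribution of a fixed budget, exactly as in real TPM data.
#'
#' @param config A `simulation_config`.
#' @param annotation Optional annotation tibble (defaults to
#'   [simulate_annotation()] under the same seed).
#' @return A list of class `allelic_sim` with elements `matrix`
#'   (raw-count `allelic_matrix`), `sample_table`, `annotation`, `truth`
#'   (compensated/silenced gene ids, per-genotype deleted intervals and
#'   expected per-allele means, base means) and `config`.
#' @export
simulate_allelic_counts <- function(config, annotation = NULL) {
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  n_genes <- nrow(annotation)
  withr::with_seed(config$seed + 1L, {
    base_mean <- stats::rlnorm(n_genes, config$base_mean_log_mu,
                               config$base_mean_log_sigma)
    # keep markers comfortably expressed so pluripotency QC is meaningful
    mk <- annotation$gene_id %in% c("Esrrb", "Nanog", "Pou5f1")
    base_mean[mk] <- pmax(base_mean[mk],
                          exp(config$base_mean_log_mu + config$base_mean_log_sigma))
    compensated <- stats::runif(n_genes) < config$pi_u
    sample_tabs <- list()
    a1 <- list()
    a2 <- list()
    expected <- list()
    deleted <- list()
    silenced_ids <- character()
    for (i in seq_len(nrow(config$genotypes))) {
      g <- config$genotypes[i, ]
      prof <- config$profiles[[g$profile]]
      em <- genotype_expected_means(annotation, base_mean, compensated, prof,
                                    config, dox = isTRUE(g$dox))
      if (any(em$silenced)) {
        silenced_ids <- union(silenced_ids, annotation$gene_id[em$silenced])
      }
      e_total <- sum(em$mu1) + sum(em$mu2)
      sdlog <- sqrt(log(1 + config$library_size_cv^2))
      lib <- config$library_size_mean / e_total *
        stats::rlnorm(g$n, -sdlog^2 / 2, sdlog)
      mu1 <- outer(em$mu1, lib)
      mu2 <- outer(em$mu2, lib)
      cnt1 <- matrix(nb_draw(mu1, config$nb_dispersion), nrow = n_genes)
      cnt2 <- matrix(nb_draw(mu2, config$nb_dispersion), nrow = n_genes)
      ids <- sprintf("%s_s%03d", g$label, seq_len(g$n))
      dimnames(cnt1) <- dimnames(cnt2) <- list(annotation$gene_id, ids)
      a1[[i]] <- cnt1
      a2[[i]] <- cnt2
      sample_tabs[[i]] <- tibble::tibble(
        sample_id = ids, genotype_label = g$label,
        condition = if (isTRUE(g$dox)) "dox+" else "dox-",
        replicate = seq_len(g$n), copy_profile_id = g$profile
      )
      expected[[g$label]] <- tibble::tibble(
        gene_id = annotation$gene_id, mu_a1 = em$mu1, mu_a2 = em$mu2
      )
      iv <- prof[prof$copies_allele1 == 0 | prof$copies_allele2 == 0, ,
                 drop = FALSE]
      deleted[[g$label]] <- tibble::as_tibble(iv)
    }
    m <- allelic_matrix(do.call(cbind, a1), do.call(cbind, a2),
                        unit = "raw_count", modality = config$modality)
    truth <- list(
      compensated_gene_ids = annotation$gene_id[compensated],
      silenced_gene_ids = silenced_ids,
      deleted_intervals = deleted,
      base_means = tibble::tibble(gene_id = annotation$gene_id,
                                  base_mean = base_mean),
      expected_means = expected
    )
    structure(list(matrix = m, sample_table = dplyr::bind_rows(sample_tabs),
                   annotation = annotation, truth = truth, config = config),
              class = "allelic_sim")
  })
}

#' @export
print.allelic_sim <- function(x, ...) {
  cat(sprintf("<allelic_sim> %d genes x %d samples; genotypes: %s\n",
              nrow(x$matrix$a1), ncol(x$matrix$a1),
              paste(unique(x$sample_table$genotype_label), collapse = ", ")))
  invisible(x)
}

#' Simulate matched protein abundances
#'
#' Protein abundance per replicate is a scaled copy of the gene's total
#' expected RNA output across alleles in that genotype, with log-normal
#' replicate noise (`protein_noise_sigma`, in log2 units). A fraction
#' `pi_protein_only` of the genes that are not RNA-compensated is compensated
#' at the protein level only: their abundance gains the factor `u` in
#' genotypes where the gene is monoallelically expressed.
#'
#' @param sim An `allelic_sim`.
#' @param n_reps Replicates per genotype.
#' @param genotypes Genotype labels to include (default: all in `sim`).
#' @param scale Abundance scale factor (LFQ-like magnitude).
#' @param dropout_rate Per-protein-per-sample probability of non-detection,
#'   default 0 (detection is exercised explicitly in tests).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return List with `proteins` (a `protein_matrix`) and `truth`
#'   (`protein_only_compensated_ids`).
#' @export
simulate_proteins <- function(sim, n_reps = 3, genotypes = NULL,
                              scale = 1e7, dropout_rate = 0, seed = NULL) {
  config <- sim$config
  seed <- seed %||% (config$seed + 2L)
  if (is.null(genotypes)) genotypes <- unique(sim$sample_table$genotype_label)
  genes <- sim$annotation$gene_id
  withr::with_seed(seed, {
    non_rna <- setdiff(genes, sim$truth$compensated_gene_ids)
    protein_only <- sample(non_rna,
                           size = round(config$pi_protein_only * length(non_rna)))
    # fixed biallelic reference denominator: abundances stay directly
    # comparable across genotypes (no per-genotype renormalization)
    ref_mean <- mean(sim$truth$base_means$base_mean *
                       (1 + config$mapping_bias_b))
    cols <- list()
    samp <- list()
    for (g in genotypes) {
      em <- sim$truth$expected_means[[g]]
      if (is.null(em)) stop("unknown genotype: ", g, call. = FALSE)
      total <- em$mu_a1 + em$mu_a2
      prof <- config$profiles[[
        sim$sample_table$copy_profile_id[
          match(g, sim$sample_table$genotype_label)]]]
      cn <- gene_copy_numbers(sim$annotation, prof)
      mono <- cn$copies_total == 1
      pfac <- ifelse(genes %in% protein_only & mono, config$u, 1)
      mu <- scale * total / ref_mean * pfac
      for (r in seq_len(n_reps)) {
        noise <- 2^stats::rnorm(length(genes), 0, config$protein_noise_sigma)
        cols[[length(cols) + 1L]] <- mu * noise
        samp[[length(samp) + 1L]] <- tibble::tibble(
          sample_id = sprintf("%s_p%02d", g, r), genotype_label = g,
          replicate = r,
          copy_profile_id = sim$sample_table$copy_profile_id[
            match(g, sim$sample_table$genotype_label)]
        )
      }
    }
    abund <- do.call(cbind, cols)
    sample_table <- dplyr::bind_rows(samp)
    dimnames(abund) <- list(paste0("P_", genes), sample_table$sample_id)
    detected <- matrix(stats::runif(length(abund)) >= dropout_rate,
                       nrow = nrow(abund), dimnames = dimnames(abund))
    abund[!detected] <- NA_real_
    pm <- protein_matrix(abund,
                         map = tibble::tibble(protein_id = paste0("P_", genes),
                                              gene_id = genes),
                         detected = detected, sample_table = sample_table)
    list(proteins = pm,
         truth = list(protein_only_compensated_ids = protein_only))
  })
}

#' Simulate per-allele ChIP-like coverage tracks
#'
#' Each allele's track is a constant background plus, over every 1 kb
#' promoter, a signal proportional to that allele's expected expression in
#' the chosen genotype, with zero-truncated Gaussian noise.
#'
#' @param sim An `allelic_sim`.
#' @param genotype Genotype label whose expected means drive the signal.
#' @param k Signal per unit of expected allelic mean.
#' @param background Constant background level.
#' @param noise_sd SD of the Gaussian noise added to each promoter.
#' @param upstream Promoter size in bp.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return Named list with `a1` and `a2` `coverage_track`s.
#' @export
simulate_coverage <- function(sim, genotype, k = 0.1, background = 0.5,
                              noise_sd = 0.25, upstream = 1000, seed = NULL) {
  config <- sim$config
  seed <- seed %||% (config$seed + 3L)
  em <- sim$truth$expected_means[[genotype]]
  if (is.null(em)) stop("unknown genotype: ", genotype, call. = FALSE)
  ann <- sim$annotation
  lens <- stats::setNames(config$chrom_plan$length, config$chrom_plan$chrom)
  withr::with_seed(seed, {
    one_allele <- function(mu) {
      prom <- promoter_region(ann, upstream = upstream,
                              chrom_lengths = lens)
      val <- pmax(0, background + k * mu +
                    stats::rnorm(nrow(ann), 0, noise_sd))
      segs <- tibble::tibble(chrom = prom$chrom, start = prom$start,
                             end = prom$end, value = val)
      build_track_with_background(segs, lens, background)
    }
    list(a1 = one_allele(em$mu_a1), a2 = one_allele(em$mu_a2))
  })
}

# assemble a stepwise track: given promoter segments and a constant
# background, emit sorted non-overlapping intervals covering each chromosome
build_track_with_background <- function(segs, chrom_lengths, background) {
  segs <- segs[order(segs$chrom, segs$start), ]
  out <- list()
  for (chrom in names(chrom_lengths)) {
    s <- segs[segs$chrom == chrom, ]
    L <- chrom_lengths[[chrom]]
    # truncate any overlap between consecutive promoters
    if (nrow(s) > 1) {
      s$start[-1] <- pmax(s$start[-1], s$end[-nrow(s)])
      s <- s[s$start < s$end, ]
    }
    pos <- 0
    rows <- vector("list", 2 * nrow(s) + 1)
    j <- 0
    for (i in seq_len(nrow(s))) {
      if (s$start[i] > pos) {
        j <- j + 1
        rows[[j]] <- c(pos, s$start[i], background)
      }
      j <- j + 1
      rows[[j]] <- c(s$start[i], min(s$end[i], L), s$value[i])
      pos <- min(s$end[i], L)
    }
    if (pos < L) {
      j <- j + 1
      rows[[j]] <- c(pos, L, background)
    }
    m <- do.call(rbind, rows[seq_len(j)])
    out[[chrom]] <- tibble::tibble(chrom = chrom, start = m[, 1],
                                   end = m[, 2], value = m[, 3])
  }
  coverage_track(dplyr::bind_rows(out), normalization = "raw")
}
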