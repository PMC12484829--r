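#' Pipeline configuration
#'
#' Bundles the simulation and analysis configurations with the output
#' location. Can also be loaded from a YAML file whose top-level keys match
#' the arguments of [simulation_config()] and [analysis_config()].
#'
#' @param seed Integer seed propagated to every stochastic stage.
#' @param outdir Output directory for stage artifacts.
#' @param sim A `simulation_config` (its seed is overridden by `seed`).
#' @param analysis An `analysis_config`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("allelicomp_"),
                            sim = simulation_config(seed = seed),
                            analysis = analysis_config()) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 analysis = analysis),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$chrom_plan)) {
    sim_args$chrom_plan <- dplyr::bind_rows(sim_args$chrom_plan)
  }
  if (!is.null(sim_args$genotypes)) {
    sim_args$genotypes <- dplyr::bind_rows(sim_args$genotypes)
  }
  ana_args <- y$analysis %||% list()
  allowed_sim <- names(formals(simulation_config))
  allowed_ana <- names(formals(analysis_config))
  bad <- c(setdiff(names(sim_args), allowed_sim),
           setdiff(names(ana_args), allowed_ana))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seed <- y$seed %||% 1L
  sim_args$seed <- seed
  pipeline_config(seed = seed,
                  outdir = y$outdir %||% tempfile("allelicomp_"),
                  sim = do.call(simulation_config, sim_args),
                  analysis = do.call(analysis_config, ana_args))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

pipeline_log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  "allelicomp", paste0(...)))
}

#' Run the analysis pipeline
#'
#' Executes the stages in order, writing deterministic TSV/JSON artifacts
#' into `config$outdir`; identical config + seed yields byte-identical
#' files. Stages: `simulate` (counts, annotation, truth), `qc` (per-sample
#' report), `xcu` (single-cell upregulation calls), `region_report`
#' (genotype contrasts of X-linked region means), `autosomal` (cis
#' silencing and trans upregulation), `protein` (differential abundance and
#' RNA-protein concordance), `chip` (promoter metaprofiles and gene-set
#' contrast), `report` (aggregate JSON summary with truth-recovery
#' metrics).
#'
#' @param config A `pipeline_config`.
#' @param stages Character vector of stages to run (order is fixed
#'   internally).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "qc", "xcu",
                                    "region_report", "autosomal", "protein",
                                    "chip", "report"),
                         quiet = FALSE) {
  all_stages <- c("simulate", "qc", "xcu", "region_report", "autosomal",
                  "protein", "chip", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) pipeline_log("INFO", ...)
  cfg_hash <- rlang::hash(config[c("seed", "sim", "analysis")])
  out <- list(config_hash = cfg_hash)
  state <- new.env(parent = emptyenv())

  need_sim <- function() {
    if (is.null(state$sim)) {
      # stages downstream of simulate re-derive it deterministically
      state$sim <- simulate_allelic_counts(config$sim)
      state$tpm <- normalize_expression(state$sim$matrix, "umi_tpm")
    }
    state$sim
  }

  for (stage in stages) {
    say("stage: ", stage)
    if (stage == "simulate") {
      sim <- need_sim()
      write_allelic_counts(sim$matrix,
                           file.path(config$outdir, "counts_allele1.tsv"),
                           file.path(config$outdir, "counts_allele2.tsv"))
      write_gene_annotation_bed(sim$annotation,
                                file.path(config$outdir, "annotation.bed"))
      readr::write_tsv(sim$sample_table,
                       file.path(config$outdir, "samples.tsv"),
                       progress = FALSE)
      write_json_artifact(
        list(compensated_gene_ids = sim$truth$compensated_gene_ids,
             silenced_gene_ids = sim$truth$silenced_gene_ids,
             config_hash = cfg_hash),
        file.path(config$outdir, "truth.json"))
      out$simulate <- sim
    } else if (stage == "qc") {
      sim <- need_sim()
      qc <- qc_report(sim$matrix, sim$annotation)
      readr::write_tsv(qc, file.path(config$outdir, "qc_report.tsv"),
                       progress = FALSE)
      out$qc <- qc
    } else if (stage == "xcu") {
      sim <- need_sim()
      calls <- call_xcu_from_experiment(state$tpm, sim$sample_table,
                                        sim$annotation,
                                        x_chrom = config$sim$x_chrom,
                                        cfg = config$analysis)
      readr::write_tsv(tidy(calls),
                       file.path(config$outdir, "xcu_calls.tsv"),
                       progress = FALSE)
      out$xcu <- calls
    } else if (stage == "region_report") {
      sim <- need_sim()
      labs <- unique(sim$sample_table$genotype_label)
      xg <- sim$annotation$gene_id[
        sim$annotation$chrom == config$sim$x_chrom]
      tot <- total_expression(state$tpm)
      vals <- purrr::map(stats::setNames(labs, labs), function(l) {
        ids <- sim$sample_table$sample_id[
          sim$sample_table$genotype_label == l]
        tot[xg, ids, drop = FALSE]
      })
      if (length(vals) >= 2) {
        rt <- test_region_compensation(vals, method = "tukey_hsd",
                                       cfg = config$analysis,
                                       region_name = config$sim$x_chrom)
        readr::write_tsv(tibble::as_tibble(rt),
                         file.path(config$outdir, "region_report.tsv"),
                         progress = FALSE)
        out$region_report <- rt
      }
    } else if (stage == "autosomal") {
      sim <- need_sim()
      if (!is.null(config$sim$silencing) &&
          any(sim$sample_table$condition == "dox+")) {
        s <- config$sim$silencing
        tgt <- if (s$allele == 1) state$tpm$a1 else state$tpm$a2
        trans <- if (s$allele == 1) state$tpm$a2 else state$tpm$a1
        plus <- sim$sample_table$sample_id[sim$sample_table$condition == "dox+"]
        minus <- sim$sample_table$sample_id[sim$sample_table$condition == "dox-"]
        sil <- call_silenced_genes(tgt[, plus, drop = FALSE],
                                   tgt[, minus, drop = FALSE])
        tss <- sim$annotation$tss[match(sil$gene_id, sim$annotation$gene_id)]
        chrom_of <- sim$annotation$chrom[match(sil$gene_id,
                                               sim$annotation$gene_id)]
        sil_tss <- tss[which(sil$silenced & chrom_of == s$chrom)]
        reg <- define_silenced_region(
          sil_tss, s$chrom,
          config$sim$chrom_plan$length[
            config$sim$chrom_plan$chrom == s$chrom])
        up <- call_trans_upregulated(trans[, plus, drop = FALSE],
                                     trans[, minus, drop = FALSE])
        readr::write_tsv(dplyr::left_join(sil, up, by = "gene_id"),
                         file.path(config$outdir, "autosomal_calls.tsv"),
                         progress = FALSE)
        readr::write_tsv(reg,
                         file.path(config$outdir, "silenced_region.tsv"),
                         progress = FALSE)
        out$autosomal <- list(silenced = sil, trans = up, region = reg)
      } else {
        say("autosomal stage skipped: no silencing in config")
      }
    } else if (stage == "protein") {
      sim <- need_sim()
      labs <- unique(sim$sample_table$genotype_label)
      want <- intersect(c("XX", "XCastOMus", "XMusOCast", "XY"), labs)
      if (length(want) >= 2) {
        pr <- simulate_proteins(sim, genotypes = want)
        pm <- filter_fully_detected(pr$proteins)
        pm_cc <- copy_number_correct_protein(pm, config$sim$profiles,
                                             sim$annotation)
        res <- NULL
        if (all(c("XX", "XCastOMus", "XY") %in% want)) {
          res <- differential_protein_abundance(pm_cc)
          readr::write_tsv(tibble::as_tibble(res),
                           file.path(config$outdir, "protein_da.tsv"),
                           progress = FALSE)
        }
        out$protein <- list(proteins = pm, corrected = pm_cc, da = res,
                            truth = pr$truth)
      } else {
        say("protein stage skipped: needs XX plus a monosomic genotype")
      }
    } else if (stage == "chip") {
      sim <- need_sim()
      labs <- unique(sim$sample_table$genotype_label)
      g <- intersect(c("XCastOMus", "XMusOCast", "XY", "XX"), labs)[1]
      cov <- simulate_coverage(sim, g)
      xg <- sim$annotation[sim$annotation$chrom == config$sim$x_chrom, ]
      active <- if (g == "XCastOMus") cov$a2 else cov$a1
      mp <- metaprofile(active, xg)
      readr::write_tsv(tibble::as_tibble(mp),
                       file.path(config$outdir, "metaprofile.tsv"),
                       progress = FALSE)
      prom <- promoter_region(xg)
      scores <- region_mean_signal(active, prom)
      readr::write_tsv(scores,
                       file.path(config$outdir, "promoter_scores.tsv"),
                       progress = FALSE)
      out$chip <- list(metaprofile = mp, promoter_scores = scores,
                       genotype = g)
    } else if (stage == "report") {
      sim <- need_sim()
      truth_comp <- sim$truth$compensated_gene_ids
      rep_list <- list(config_hash = cfg_hash, seed = config$seed,
                       n_genes = nrow(sim$annotation),
                       n_samples = nrow(sim$sample_table))
      if (!is.null(out$xcu)) {
        called <- out$xcu$gene_id[which(out$xcu$upregulated)]
        xg <- sim$annotation$gene_id[
          sim$annotation$chrom == config$sim$x_chrom]
        truth_x <- intersect(truth_comp, xg)
        rep_list$xcu <- list(
          n_called = length(called),
          sensitivity = if (length(truth_x)) {
            length(intersect(called, truth_x)) / length(truth_x)
          } else NA,
          precision = if (length(called)) {
            length(intersect(called, truth_x)) / length(called)
          } else NA
        )
      }
      if (!is.null(out$qc)) {
        rep_list$qc <- list(n_pass_umi = sum(out$qc$pass_umi_filter))
      }
      write_json_artifact(rep_list, file.path(config$outdir, "report.json"))
      out$report <- rep_list
    }
  }
  invisible(out)
}
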