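mat1 <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

test_that("XCU calling tests active-allele expression against half of XX", {
  mono <- mat1(gA = c(2.0, 2.1, 1.9), gB = c(1, 1, 1),
               gC = c(1.19, 1.19, 1.19))
  xx <- mat1(gA = c(2, 2, 2), gB = c(2, 2, 2), gC = c(2, 2, 2))
  calls <- call_xcu_genes(mono, xx)
  a <- calls[calls$gene_id == "gA", ]
  # equal-variance oracle: t = (2 - 1) / (0.1 / sqrt(3)) ~ 17.3
  expect_equal(a$fold_change, 2)
  expect_lt(a$p_value, 0.05)
  expect_true(a$upregulated)
  b <- calls[calls$gene_id == "gB", ]
  expect_equal(b$fold_change, 1)
  expect_false(b$upregulated)
  # the fold-change gate blocks significant-but-small effects
  cc <- calls[calls$gene_id == "gC", ]
  expect_lt(cc$p_value, 0.05)
  expect_false(cc$upregulated)
})

test_that("XCU calling reports NA for an all-zero reference", {
  mono <- mat1(g = c(1, 2, 1))
  xx <- mat1(g = c(0, 0, 0))
  calls <- call_xcu_genes(mono, xx)
  expect_true(is.na(calls$p_value))
  expect_true(is.na(calls$upregulated))
})

test_that("bulk selection filters on reference TPM and uses a strict FC gate", {
  xo <- mat1(hi = c(15, 15), edge = c(12, 12), low = c(9, 9))
  xx <- mat1(hi = c(10, 10), edge = c(10, 10), low = c(4, 4))
  sel <- select_upregulated_bulk(xo, xx)
  expect_true(sel$selected[sel$gene_id == "hi"])
  expect_false(sel$selected[sel$gene_id == "edge"])  # FC exactly 1.2
  expect_false(sel$selected[sel$gene_id == "low"])   # below TPM 5 in ref
  expect_false(sel$expressed[sel$gene_id == "low"])
})

test_that("region tests pair by gene, correct by Bonferroni, and abstain when sparse", {
  set.seed(11)
  g <- matrix(rlnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
  vals <- list(XX = g, XO = g * 1.5, Del = g * 1.4)
  rt <- test_region_compensation(vals)
  expect_equal(nrow(rt), 3)  # C(3,2) pairs
  expect_equal(rt$p_adj, pmin(1, rt$p_value * 3))
  # identical matrices: all differences zero -> degenerate-sd convention p=1
  same <- test_region_compensation(list(a = g, b = g))
  expect_equal(same$p_value, 1)
  sparse <- test_region_compensation(list(a = g[1:8, ], b = g[1:8, ]))
  expect_true(all(is.na(sparse$p_value)))
  expect_false(attr(sparse, "tested"))
  expect_equal(attr(sparse, "reason"), "too few genes")
  # tukey variant runs on per-replicate region means
  tk <- test_region_compensation(vals, method = "tukey_hsd")
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("Tukey HSD reduces to the pooled t-test at k = 2", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(6 + i)
    y <- rnorm(5, 0.8)
    th <- tukey_hsd(list(x = x, y = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(th$p_adj, tt$p.value, tolerance = 1e-6)
    expect_equal(th$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-9)
  }
})

test_that("Tukey HSD matches the base aov reference across k = 3 designs", {
  set.seed(31)
  for (i in 1:5) {
    g <- list(a = rnorm(4 + i), b = rnorm(6, 0.5), c = rnorm(5, 1))
    th <- tukey_hsd(g)
    base <- TukeyHSD(aov(y ~ f, data.frame(
      y = unlist(g), f = rep(names(g), lengths(g)))))$f
    expect_equal(th$p_adj, unname(base[, "p adj"]), tolerance = 1e-9)
    expect_equal(th$diff, unname(base[, "diff"]), tolerance = 1e-9)
  }
})

test_that("Tukey HSD handles identical and zero-variance groups", {
  g <- rep(list(c(1, 2, 3)), 3)
  names(g) <- c("a", "b", "c")
  th <- tukey_hsd(g)
  expect_true(all(th$p_adj > 0.999))
  degen <- tukey_hsd(list(a = c(1, 1), b = c(2, 2)))
  expect_lt(degen$p_adj, .Machine$double.eps)
  expect_error(tukey_hsd(list(a = 1:3)), "two groups")
  expect_error(tukey_hsd(list(a = 1, b = 2)), "two values")
})

test_that("p-value adjustment matches hand-computed step-up and Bonferroni", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.03, 0.4), "bonferroni"), c(0.06, 0.8))
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("BH output is monotone in sorted order and permutation-invariant", {
  set.seed(41)
  p <- runif(30)
  adj <- adjust_pvalues(p, "bh")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(30)
  expect_equal(adjust_pvalues(p[perm], "bh"), adj[perm])
})

test_that("chi-square matches the hand formula and is transpose-invariant", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- chi_square_2x2(tab)
  # n (ad - bc)^2 / (r1 r2 c1 c2) = 60 * (400 - 100)^2 / 30^4
  expect_equal(res$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4,
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(t(tab))$statistic, res$statistic)
  even <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(1, 1, 0, 0), 2)), "zero margin")
})

test_that("cis-silencing calls follow the 0.15 fold-change rule", {
  plus <- mat1(sil = c(1, 1), edge = c(2, 2), keep = c(9, 11), off = c(1, 1))
  minus <- mat1(sil = c(10, 10), edge = c(10, 10), keep = c(10, 10),
                off = c(0, 0))
  r <- call_silenced_genes(plus, minus)
  expect_true(r$silenced[r$gene_id == "sil"])
  expect_false(r$silenced[r$gene_id == "edge"])  # 0.20 >= 0.15
  expect_false(r$silenced[r$gene_id == "keep"])
  expect_true(is.na(r$silenced[r$gene_id == "off"]))
})

test_that("silenced-region detection finds dense windows and extends to the telomere", {
  set.seed(51)
  tss <- runif(120, 80e6, 160e6)
  reg <- define_silenced_region(tss, "chr3", 160e6)
  expect_equal(nrow(reg), 1)
  expect_lt(abs(reg$start - 80e6), 10e6)
  expect_equal(reg$end, 160e6)
  expect_warning(r0 <- define_silenced_region(numeric(), "chr3", 160e6),
                 "no silenced genes")
  expect_equal(nrow(r0), 0)
  fb <- define_silenced_region(tss, "chr3", 160e6, detect = FALSE,
                               fallback = list(chrom = "chr3", start = 80e6,
                                               end = 160e6))
  expect_equal(fb$start, 80e6)
  expect_equal(fb$end, 160e6)
})

test_that("trans-upregulation uses the log2 rule by default, linear optionally", {
  plus <- mat1(up = c(4.5, 4.5), flat = c(3, 3))
  minus <- mat1(up = c(3, 3), flat = c(3, 3))
  r <- call_trans_upregulated(plus, minus)
  expect_true(r$trans_upregulated[r$gene_id == "up"])   # log2(1.5) ~ 0.585
  expect_false(r$trans_upregulated[r$gene_id == "flat"])
  lin <- call_trans_upregulated(plus, minus, mode = "linear")
  expect_true(all(lin$trans_upregulated))  # linear FC > 0.5 is near-vacuous
})

test_that("gene-set proportion comparison builds the 2x2 test and degenerates cleanly", {
  up <- paste0("u", 1:30)
  non <- paste0("n", 1:60)
  annset <- c(up[1:20], non[1:10])
  r <- compare_gene_set_proportions(up, non, annset)
  expect_equal(r$proportions$proportion, c(20 / 30, 10 / 60))
  hand <- chi_square_2x2(matrix(c(20, 10, 10, 50), 2, byrow = TRUE))
  expect_equal(r$test$statistic, hand$statistic)
  full <- compare_gene_set_proportions(up, non, c(up, non))
  expect_equal(full$test$statistic, 0)
  expect_equal(full$test$p_value, 1)
  expect_error(compare_gene_set_proportions(character(), non, annset),
               "empty")
})

test_that("XCU recovery from a simulated experiment meets power expectations", {
  cfg <- small_sim_config(seed = 61)
  sim <- simulate_allelic_counts(cfg)
  tpm <- normalize_expression(sim$matrix, "umi_tpm")
  calls <- call_xcu_from_experiment(tpm, sim$sample_table, sim$annotation)
  xg <- sim$annotation$gene_id[sim$annotation$chrom == "chrX"]
  truth <- intersect(sim$truth$compensated_gene_ids, xg)
  called <- calls$gene_id[which(calls$upregulated)]
  expect_gt(length(intersect(called, truth)) / length(truth), 0.7)
  expect_gt(length(intersect(called, truth)) / length(called), 0.85)
  expect_s3_class(tidy(calls), "tbl_df")
  expect_equal(glance(calls)$n_upregulated, length(called))
})

test_that("trans-upregulated genes are recovered in a bulk cis-silencing design", {
  cfg <- simulation_config(
    seed = 71, modality = "bulk",
    chrom_plan = tibble::tibble(chrom = c("chrX", "chr1", "chr3"),
                                length = c(171e6, 195e6, 160e6),
                                n_genes = c(60L, 200L, 250L)),
    genotypes = tibble::tibble(label = c("dox_plus", "dox_minus"),
                               n = c(3L, 3L), profile = "XX",
                               dox = c(TRUE, FALSE)),
    silencing = list(chrom = "chr3", start = 80e6, end = 160e6,
                     allele = 2))
  sim <- simulate_allelic_counts(cfg)
  tpm <- normalize_expression(sim$matrix, "umi_tpm")
  st <- sim$sample_table
  plus <- st$sample_id[st$condition == "dox+"]
  minus <- st$sample_id[st$condition == "dox-"]
  # the targeted Cast allele collapses to the silencing residual
  sil <- call_silenced_genes(tpm$a2[, plus], tpm$a2[, minus])
  truth_sil <- sim$truth$silenced_gene_ids
  expect_gt(mean(truth_sil %in% sil$gene_id[which(sil$silenced)]), 0.9)
  # compensated silenced genes upregulate the trans (Mus) allele
  up <- call_trans_upregulated(tpm$a1[, plus], tpm$a1[, minus])
  truth_up <- intersect(truth_sil, sim$truth$compensated_gene_ids)
  called <- up$gene_id[which(up$trans_upregulated)]
  expect_gte(mean(truth_up %in% called), 0.8)
  # genes outside the silenced region stay quiet on both alleles
  outside <- setdiff(
    sim$annotation$gene_id[sim$annotation$chrom == "chr3"], truth_sil)
  expect_lt(mean(outside %in% called), 0.1)
})
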