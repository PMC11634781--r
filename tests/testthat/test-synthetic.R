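test_that("gene annotation is deterministic, sorted, non-overlapping", {
  cfg <- toy_sim_config()
  g1 <- simulate_gene_annotation(cfg)
  g2 <- simulate_gene_annotation(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), cfg$n_genes)
  expect_true(all(g1$strand %in% c("+", "-")))
  expect_true(all(g1$tss >= g1$start & g1$tss < g1$end))
  ## sorted and pairwise non-overlapping within chromosome
  for (ch in unique(g1$chrom)) {
    sub <- g1[g1$chrom == ch, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(simulate_gene_annotation(
    sim_config(n_genes = 100, n_chroms = 1, chrom_length = 40000 * 10,
               planted_genes = c(restored_up = 5, restored_down = 5,
                                 memory_up = 5, memory_down = 5),
               planted_regions = c(gain_maintained = 2))),
    "too small")
})

test_that("100 genes on one 10 Mb chromosome do not overlap (interval check)", {
  cfg <- sim_config(n_genes = 100, n_chroms = 1, chrom_length = 1e7,
                    planted_genes = c(restored_up = 5, restored_down = 5,
                                      memory_up = 5, memory_down = 5),
                    planted_regions = c(gain_maintained = 5, gain_lost = 5),
                    qc_min_features = 10)
  g <- simulate_gene_annotation(cfg)
  expect_equal(nrow(g), 100L)
  ## brute-force pairwise overlap check
  ov <- outer(seq_len(100), seq_len(100), function(i, j)
    g$start[i] < g$end[j] & g$start[j] < g$end[i] & i != j)
  expect_false(any(ov))
})

test_that("single-nucleus counts are deterministic with planted effects", {
  cfg <- toy_sim_config()
  genes <- simulate_gene_annotation(cfg)
  s1 <- simulate_sn_counts(cfg, genes)
  s2 <- simulate_sn_counts(cfg, genes)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_equal(nrow(s1$truth), cfg$n_genes)
  expect_true(all(table(s1$truth$class)[names(cfg$planted_genes)] ==
                    cfg$planted_genes))
  ## zero effect -> planted classes still labelled but distributionally null
  cfg0 <- toy_sim_config(effect_size_log2fc = 0)
  s0 <- simulate_sn_counts(cfg0, simulate_gene_annotation(cfg0))
  meta <- s0$cell_meta
  mem <- s0$truth$gene[s0$truth$class == "memory_up"]
  mH <- Matrix::rowMeans(s0$counts[mem, meta$condition == "H"])
  mC <- Matrix::rowMeans(s0$counts[mem, meta$condition == "C"])
  expect_lt(abs(mean(mH) / mean(mC) - 1), 0.2)
  expect_error(simulate_sn_counts(
    sim_config(conditions = c("C", "CC")), genes), "obese")
})

test_that("planted memory genes show the configured fold change (Monte Carlo)", {
  cfg <- sim_config(n_genes = 400, n_chroms = 1, chrom_length = 400 * 40000,
                    n_cells_per_condition = 300,
                    conditions = c("C", "CC", "H", "HC"),
                    planted_genes = c(restored_up = 20, restored_down = 20,
                                      memory_up = 20, memory_down = 20),
                    effect_size_log2fc = 1.5, qc_min_features = 10,
                    seed = 77)
  genes <- simulate_gene_annotation(cfg)
  s <- simulate_sn_counts(cfg, genes)
  meta <- s$cell_meta
  mem_up <- s$truth$gene[s$truth$class == "memory_up"]
  ratio <- Matrix::rowMeans(s$counts[mem_up, meta$condition == "HC"]) /
    Matrix::rowMeans(s$counts[mem_up, meta$condition == "CC"])
  ## pooled over 20 genes x 300 cells: HC/CC ratio within [2^1.2, 2^1.8]
  expect_gt(mean(ratio), 2^1.2)
  expect_lt(mean(ratio), 2^1.8)
  ## restored genes: shifted in H, null in HC
  res_up <- s$truth$gene[s$truth$class == "restored_up"]
  r_h <- mean(Matrix::rowMeans(s$counts[res_up, meta$condition == "H"]) /
                Matrix::rowMeans(s$counts[res_up, meta$condition == "C"]))
  r_hc <- mean(Matrix::rowMeans(s$counts[res_up, meta$condition == "HC"]) /
                 Matrix::rowMeans(s$counts[res_up, meta$condition == "CC"]))
  expect_gt(r_h, 2^1.2)
  expect_lt(abs(r_hc - 1), 0.25)
})

test_that("NB marginals match the configured mean and dispersion", {
  ## moment check at n >= 10,000 draws through the generator machinery
  cfg <- sim_config(n_genes = 40, n_chroms = 1, chrom_length = 40 * 40000,
                    n_cells_per_condition = 300,
                    conditions = c("C", "H"),
                    planted_genes = c(restored_up = 0, restored_down = 0,
                                      memory_up = 0, memory_down = 0),
                    planted_regions = c(gain_maintained = 2),
                    library_size_cv = 0, nb_dispersion = 0.3,
                    baseline_mean_range = c(20, 20),
                    qc_min_features = 2, seed = 5)
  s <- simulate_sn_counts(cfg, simulate_gene_annotation(cfg))
  x <- as.vector(as.matrix(s$counts))  # 40 genes x 600 cells = 24,000 draws
  expect_lt(abs(mean(x) - 20) / 20, 0.05)
  phi_hat <- (stats::var(x) - mean(x)) / mean(x)^2
  expect_lt(abs(phi_hat - 0.3), 0.06)
})

test_that("region counts realize planted trajectory classes", {
  ## library variation off: the moment check isolates the planted effect
  cfg <- toy_sim_config(library_size_cv = 0)
  genes <- simulate_gene_annotation(cfg)
  r1 <- simulate_region_counts(cfg, genes)
  r2 <- simulate_region_counts(cfg, genes)
  expect_identical(r1$counts, r2$counts)
  ## class labels partition (modality, region) space
  expect_equal(nrow(r1$region_class),
               length(r1$counts) * nrow(r1$regions))
  expect_false(any(duplicated(
    r1$region_class[c("modality", "region")])))
  ## gain_maintained with lfc = 2 -> H/C and HC/CC mean ratios near 4
  sm <- r1$sample_meta
  tot <- c(H = 0, C = 0, HC = 0, CC = 0)
  for (mod in names(r1$counts)) {
    rc <- r1$region_class[r1$region_class$modality == mod, ]
    gm <- rc$region[rc$class == "gain_maintained"]
    if (length(gm) == 0) next
    cnt <- r1$counts[[mod]][gm, , drop = FALSE]
    for (cd in names(tot)) {
      tot[cd] <- tot[cd] + sum(cnt[, sm$condition == cd])
    }
  }
  ## pooled over all gain_maintained loci: both contrasts near 2^2 = 4
  expect_gt(tot[["H"]] / tot[["C"]], 2^1.6)
  expect_lt(tot[["H"]] / tot[["C"]], 2^2.4)
  expect_gt(tot[["HC"]] / tot[["CC"]], 2^1.6)
  expect_lt(tot[["HC"]] / tot[["CC"]], 2^2.4)
  ## stable regions: all condition means equal within noise
  rc0 <- r1$region_class[r1$region_class$modality == "H3K4me3", ]
  st <- rc0$region[rc0$class == "stable"]
  cnt <- r1$counts[["H3K4me3"]][st, ]
  m_h <- sum(cnt[, sm$condition == "H"]); m_c <- sum(cnt[, sm$condition == "C"])
  expect_lt(abs(m_h / m_c - 1), 0.25)
  ## explained_fraction = 0 -> no links
  cfg0 <- toy_sim_config(explained_fraction = 0)
  r0 <- simulate_region_counts(cfg0, simulate_gene_annotation(cfg0))
  expect_equal(nrow(r0$explanation_link), 0L)
  ## links only reference memory genes and persistent classes
  truth <- simulate_sn_counts(cfg, genes)$truth
  mem <- truth$gene[grepl("^memory", truth$class)]
  expect_true(all(r1$explanation_link$gene %in% mem))
  for (i in seq_len(nrow(r1$explanation_link))) {
    cls <- r1$region_class$class[
      r1$region_class$modality == r1$explanation_link$modality[i] &
        r1$region_class$region == r1$explanation_link$region[i]]
    expect_true(cls %in% c("gain_maintained", "loss_maintained"))
  }
})

test_that("binned tracks plant enhancer bins exactly by the mark rule", {
  cfg <- toy_sim_config()
  genes <- simulate_gene_annotation(cfg)
  genome <- c(chr1 = cfg$chrom_length)
  prom <- make_promoters(genes, genome = genome)
  tr <- simulate_binned_tracks(cfg, prom)
  expect_equal(nrow(tr$bins), cfg$chrom_length / cfg$bin_width)
  b <- tr$bins
  qual <- b$H3K4me1 == 1 & b$H3K27ac == 1 & b$ATAC == 1 & b$H3K4me3 == 0
  planted <- paste(tr$enhancer_bins$chrom, tr$enhancer_bins$start)
  allq <- paste(b$chrom, b$start)[qual]
  ## planted bins all satisfy the conjunction
  expect_true(all(planted %in% allq))
  ## planted bins never overlap promoters
  if (nrow(tr$enhancer_bins) > 0) {
    enh_gr <- GenomicRanges::GRanges(
      tr$enhancer_bins$chrom,
      IRanges::IRanges(tr$enhancer_bins$start + 1L, tr$enhancer_bins$end))
    expect_false(any(IRanges::overlapsAny(enh_gr, prom)))
  }
  ## qualifying bins outside promoters are exactly the planted set
  bin_gr <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  outside <- !IRanges::overlapsAny(bin_gr, prom)
  expect_equal(sum(qual & outside), nrow(tr$enhancer_bins))
  ## determinism
  expect_identical(simulate_binned_tracks(cfg, prom)$bins, tr$bins)
})
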