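#' @importFrom stats rnbinom runif rlnorm rgeom rbinom
NULL

## Condition semantics used by the generator. Obese-like conditions carry
## the obesity effect; weight-loss conditions additionally carry the effect
## for memory (but not restored) genes; everything else is a control.
OBESE_CONDITIONS <- c("H", "HH", "HCH")
WL_CONDITIONS <- c("HC", "HHC")
CONTROL_CONDITIONS <- c("C", "CC", "CCC", "CCH")
ALL_CONDITIONS <- c(CONTROL_CONDITIONS, OBESE_CONDITIONS, WL_CONDITIONS)
MODALITIES <- c("H3K4me3", "H3K27me3", "H3K27ac", "H3K4me1", "ATAC")

#' Configuration for the synthetic obesogenic-memory study generator
#'
#' Defaults describe the study conditions emulated throughout the package:
#' a nine-arm mouse design (controls C/CC/CCC/CCH, obese H/HH, weight loss
#' HC/HHC, rebound HCH), negative-binomial counts with per-cell library
#' size variation, and planted ground-truth classes for genes and regions.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms,chrom_length Genome shape (default 2 x 40 Mb);
#'   `chrom_length` must be a multiple of `bin_width`.
#' @param n_cells_per_condition Nuclei per condition (default 300).
#' @param cell_types Named vector of cell-type mixing proportions
#'   (default a single adipocyte population).
#' @param conditions Ordered subset of the nine condition labels.
#' @param n_replicates_per_condition Replicates per condition for region
#'   assays (default 3).
#' @param region_conditions Conditions profiled by the region assays
#'   (default C, CC, H, HC: the obese arm and its controls).
#' @param planted_genes Named counts for classes `restored_up`,
#'   `restored_down`, `memory_up`, `memory_down`; remaining genes are null.
#' @param planted_regions Named counts for region trajectory classes
#'   `gain_maintained`, `gain_lost`, `loss_maintained`, `loss_regained`,
#'   `wl_only`, assigned to loci of null genes (on top of the
#'   explanation-linked persistent regions); everything else is stable.
#' @param effect_size_log2fc Planted gene effect in log2 units
#'   (default 1.5).
#' @param region_effect_log2fc Planted region effect (default 2).
#' @param nb_dispersion NB dispersion phi for single-nucleus counts,
#'   `Var = mu + phi mu^2` (default 0.1).
#' @param region_nb_dispersion NB dispersion for region counts
#'   (default 0.05).
#' @param baseline_mean_range Range of per-gene baseline mean counts per
#'   cell; sampled log-uniformly (default c(0.2, 4)).
#' @param region_mean_range Range of per-region baseline mean counts per
#'   replicate (default c(50, 200)).
#' @param library_size_cv Coefficient of variation of log-normal per-cell /
#'   per-sample library factors (default 0.3).
#' @param explained_fraction Fraction of planted memory genes given a
#'   persistent epigenetic link (default 0.7).
#' @param bin_width Track bin width in bp (default 200).
#' @param min_planted_baseline Genes must have baseline mean at least this
#'   to receive a planted DEG class (default 0.5 counts/cell; DEGs callable
#'   at the study thresholds are expressed genes).
#' @param qc_min_features,qc_max_features,qc_max_umi Cell-QC thresholds the
#'   pipeline applies (defaults 500, 3000, 40000; scale `qc_min_features`
#'   down for toy gene universes smaller than 500).
#' @param seed Integer seed controlling all randomness (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_chroms = 2,
                       chrom_length = 4e7,
                       n_cells_per_condition = 300,
                       cell_types = c(adipocyte = 1),
                       conditions = ALL_CONDITIONS,
                       n_replicates_per_condition = 3,
                       region_conditions = c("C", "CC", "H", "HC"),
                       planted_genes = c(restored_up = 75,
                                         restored_down = 75,
                                         memory_up = 75,
                                         memory_down = 75),
                       planted_regions = c(gain_maintained = 60,
                                           gain_lost = 60,
                                           loss_maintained = 60,
                                           loss_regained = 60,
                                           wl_only = 40),
                       effect_size_log2fc = 1.5,
                       region_effect_log2fc = 2,
                       nb_dispersion = 0.1,
                       region_nb_dispersion = 0.05,
                       baseline_mean_range = c(0.2, 4),
                       region_mean_range = c(50, 200),
                       library_size_cv = 0.3,
                       explained_fraction = 0.7,
                       bin_width = 200,
                       min_planted_baseline = 0.5,
                       qc_min_features = 500,
                       qc_max_features = 3000,
                       qc_max_umi = 40000,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_chroms = n_chroms,
              chrom_length = chrom_length,
              n_cells_per_condition = n_cells_per_condition,
              cell_types = cell_types, conditions = conditions,
              n_replicates_per_condition = n_replicates_per_condition,
              region_conditions = region_conditions,
              planted_genes = planted_genes,
              planted_regions = planted_regions,
              effect_size_log2fc = effect_size_log2fc,
              region_effect_log2fc = region_effect_log2fc,
              nb_dispersion = nb_dispersion,
              region_nb_dispersion = region_nb_dispersion,
              baseline_mean_range = baseline_mean_range,
              region_mean_range = region_mean_range,
              library_size_cv = library_size_cv,
              explained_fraction = explained_fraction,
              bin_width = bin_width,
              min_planted_baseline = min_planted_baseline,
              qc_min_features = qc_min_features,
              qc_max_features = qc_max_features,
              qc_max_umi = qc_max_umi,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (!all(cfg$conditions %in% ALL_CONDITIONS)) {
    stop("unknown condition label(s): ",
         paste(setdiff(cfg$conditions, ALL_CONDITIONS), collapse = ", "))
  }
  if (!all(cfg$region_conditions %in% ALL_CONDITIONS)) {
    stop("unknown region condition label(s)")
  }
  if (!any(cfg$conditions %in% CONTROL_CONDITIONS) ||
      !any(cfg$conditions %in% c(OBESE_CONDITIONS, WL_CONDITIONS))) {
    stop("conditions must include at least one control and one ",
         "obese/weight-loss condition")
  }
  if (sum(cfg$planted_genes) > cfg$n_genes) {
    stop("planted gene classes exceed n_genes")
  }
  if (sum(cfg$planted_regions) > 2 * cfg$n_genes) {
    stop("planted region classes exceed the number of regions")
  }
  if (cfg$explained_fraction < 0 || cfg$explained_fraction > 1) {
    stop("explained_fraction must lie in [0, 1]")
  }
  if (cfg$nb_dispersion < 0 || cfg$region_nb_dispersion < 0) {
    stop("dispersions must be >= 0")
  }
  if (cfg$effect_size_log2fc < 0) stop("effect_size_log2fc must be >= 0")
  if (cfg$chrom_length %% cfg$bin_width != 0) {
    stop("bin_width must divide chrom_length")
  }
  if (abs(sum(cfg$cell_types) - 1) > 1e-8) {
    stop("cell_types proportions must sum to 1")
  }
  if (cfg$n_replicates_per_condition < 2) {
    stop("n_replicates_per_condition must be >= 2")
  }
  invisible(cfg)
}

## Genes are laid out on fixed 40-kb slots with jitter, leaving room for a
## promoter window upstream and a distal enhancer 4.5-9 kb from the TSS on
## the side away from the gene body; the layout guarantees that the distal
## enhancer's closest gene (body or TSS) is its host gene.
SLOT <- 40000L

#' Simulate a non-overlapping gene annotation
#'
#' @param config A [sim_config()].
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `tss`, sorted by (chrom, start).
#' @export
simulate_gene_annotation <- function(config) {
  validate_sim_config(config)
  slots_per_chrom <- config$chrom_length %/% SLOT
  if (config$n_genes > slots_per_chrom * config$n_chroms) {
    stop("genome too small to place ", config$n_genes,
         " genes on ", SLOT, "-bp slots")
  }
  set.seed(config$seed)
  ## even split of genes across chromosomes
  per_chrom <- table(factor(rep(seq_len(config$n_chroms),
                                length.out = config$n_genes),
                            levels = seq_len(config$n_chroms)))
  rows <- list()
  idx <- 1L
  for (ch in seq_len(config$n_chroms)) {
    ng <- as.integer(per_chrom[[ch]])
    if (ng == 0L) next
    slot_start <- (seq_len(ng) - 1L) * SLOT
    gstart <- slot_start + 12000L +
      as.integer(floor(runif(ng, 0, 6000)))
    glen <- as.integer(floor(runif(ng, 2000, 10000)))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    rows[[ch]] <- data.frame(
      gene_id = sprintf("gene%05d", idx:(idx + ng - 1L)),
      chrom = paste0("chr", ch),
      start = gstart, end = gstart + glen, strand = strand)
    idx <- idx + ng
  }
  genes <- do.call(rbind, rows)
  genes$tss <- gene_tss(genes)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  genes
}

## Per-gene class labels with planted effects confined to genes expressed
## above the callable floor.
assign_gene_classes <- function(config, base_mean) {
  classes <- rep("null", config$n_genes)
  eligible <- which(base_mean >= config$min_planted_baseline)
  need <- sum(config$planted_genes)
  if (length(eligible) < need) {
    stop("not enough genes above min_planted_baseline to plant DEG classes")
  }
  chosen <- sample(eligible, need)
  classes[chosen] <- rep(names(config$planted_genes),
                         times = config$planted_genes)
  classes
}

## log2 shift applied to a gene class in a condition
gene_shift <- function(class, condition, lfc) {
  sgn <- ifelse(grepl("_up$", class), 1, ifelse(grepl("_down$", class), -1, 0))
  on <- (grepl("^memory", class) &
           condition %in% c(OBESE_CONDITIONS, WL_CONDITIONS)) |
    (grepl("^restored", class) & condition %in% OBESE_CONDITIONS)
  ifelse(on, sgn * lfc, 0)
}

#' Simulate single-nucleus counts with planted restored/memory genes
#'
#' Counts are negative binomial with per-gene baseline means (log-uniform
#' over `baseline_mean_range`), log-normal per-cell library factors, and
#' planted log2 shifts: memory genes are shifted by `effect_size_log2fc`
#' in obese-like (H, HH, HCH) and weight-loss (HC, HHC) conditions;
#' restored genes in obese-like conditions only; null genes never.
#'
#' @param config A [sim_config()].
#' @param genes Output of [simulate_gene_annotation()].
#' @return List with `counts` (sparse genes x cells `dgCMatrix`),
#'   `cell_meta` (`data.frame`: `cell`, `condition`, `cell_type`) and
#'   `truth` (`data.frame`: `gene`, `class`).
#' @export
simulate_sn_counts <- function(config, genes) {
  validate_sim_config(config)
  stopifnot(nrow(genes) == config$n_genes)
  set.seed(config$seed + 1L)
  lo <- log(config$baseline_mean_range[1])
  hi <- log(config$baseline_mean_range[2])
  base_mean <- exp(runif(config$n_genes, lo, hi))
  classes <- assign_gene_classes(config, base_mean)
  n_cells <- config$n_cells_per_condition
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  blocks <- list()
  meta <- list()
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  for (cond in config$conditions) {
    shift <- gene_shift(classes, cond, config$effect_size_log2fc)
    mu_gene <- base_mean * 2^shift
    lib <- rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mu <- outer(mu_gene, lib)
    cnt <- matrix(rnbinom(length(mu), mu = mu, size = size),
                  nrow = config$n_genes)
    blocks[[cond]] <- cnt
    ct <- sample(names(config$cell_types), n_cells, replace = TRUE,
                 prob = config$cell_types)
    meta[[cond]] <- data.frame(
      cell = paste0(cond, "_cell", seq_len(n_cells)),
      condition = cond, cell_type = ct)
  }
  counts <- do.call(cbind, blocks)
  cell_meta <- do.call(rbind, meta)
  rownames(cell_meta) <- NULL
  dimnames(counts) <- list(genes$gene_id, cell_meta$cell)
  list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "CsparseMatrix"), "generalMatrix"),
       cell_meta = cell_meta,
       truth = data.frame(gene = genes$gene_id, class = classes))
}

## Region layout: a promoter region per gene plus one distal enhancer per
## gene, placed 4.5-9 kb from the TSS away from the gene body.
region_layout <- function(config, genes) {
  set.seed(config$seed + 2L)
  tss0 <- genes$tss
  prom <- data.frame(
    region = paste0("prom_", genes$gene_id),
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(0, tss0 - 2000L), end = tss0 + 2000L,
    locus_type = "promoter")
  d <- as.integer(floor(runif(nrow(genes), 4500, 9000)))
  w <- 600L
  enh_start <- ifelse(genes$strand == "+", tss0 - d - w, tss0 + d)
  enh <- data.frame(
    region = paste0("enh_", genes$gene_id),
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = pmax(0, enh_start), end = pmax(0, enh_start) + w,
    locus_type = "enhancer")
  rbind(prom, enh)
}

## class multiplier per region class per condition (log2 units)
region_shift <- function(class, condition, lfc) {
  up_obese <- class %in% c("gain_maintained", "gain_lost")
  up_wl <- class %in% c("gain_maintained", "wl_only")
  down_obese <- class %in% c("loss_maintained", "loss_regained")
  down_wl <- class == "loss_maintained"
  obese <- condition %in% OBESE_CONDITIONS
  wl <- condition %in% WL_CONDITIONS
  ifelse(obese & up_obese, lfc,
         ifelse(obese & down_obese, -lfc,
                ifelse(wl & up_wl, lfc,
                       ifelse(wl & down_wl, -lfc, 0))))
}

#' Simulate per-modality region count matrices with planted trajectories
#'
#' Builds a shared region layout (a promoter and a distal enhancer per
#' gene) and, for each of the five modalities (H3K4me3, H3K27me3, H3K27ac,
#' H3K4me1, ATAC), an NB count matrix over
#' `region_conditions x n_replicates_per_condition` samples. A configured
#' fraction of planted memory genes receive a direction-consistent
#' persistent region (the explanation links); further trajectory classes
#' from `planted_regions` are planted on loci of null genes; all remaining
#' regions are stable.
#'
#' @param config A [sim_config()].
#' @param genes Output of [simulate_gene_annotation()].
#' @param gene_truth `truth` component of [simulate_sn_counts()]; if
#'   omitted, gene classes are re-derived (same seed, identical result).
#' @return List with `regions` (layout `data.frame`), `counts` (named list
#'   of region x sample matrices per modality), `sample_meta`
#'   (`data.frame`: `sample`, `condition`, `replicate`), `region_class`
#'   (`data.frame`: `modality`, `region`, `class`) and `explanation_link`
#'   (`data.frame`: `gene`, `modality`, `region`, `locus_type`,
#'   `direction`).
#' @export
simulate_region_counts <- function(config, genes, gene_truth = NULL) {
  validate_sim_config(config)
  if (is.null(gene_truth)) {
    set.seed(config$seed + 1L)
    lo <- log(config$baseline_mean_range[1])
    hi <- log(config$baseline_mean_range[2])
    base_mean <- exp(runif(config$n_genes, lo, hi))
    gene_truth <- data.frame(gene = genes$gene_id,
                             class = assign_gene_classes(config, base_mean))
  }
  layout <- region_layout(config, genes)
  set.seed(config$seed + 3L)
  region_class <- expand.grid(modality = MODALITIES,
                              region = layout$region,
                              stringsAsFactors = FALSE)
  region_class$class <- "stable"
  key <- function(m, r) paste(m, r, sep = "\r")
  cls_env <- new.env(parent = emptyenv())
  ## 1) explanation links on memory genes
  mem_genes <- gene_truth$gene[grepl("^memory", gene_truth$class)]
  mem_dir <- ifelse(grepl("_up$",
                          gene_truth$class[grepl("^memory",
                                                 gene_truth$class)]),
                    "up", "down")
  n_link <- round(config$explained_fraction * length(mem_genes))
  link_rows <- list()
  if (n_link > 0) {
    picked <- sample(seq_along(mem_genes), n_link)
    for (j in picked) {
      g <- mem_genes[j]
      locus <- sample(c("promoter", "enhancer"), 1)
      region <- paste0(if (locus == "promoter") "prom_" else "enh_", g)
      ## direction-consistent persistent mark: activating gain (or
      ## repressive loss) for up-memory genes, mirrored for down
      use_repressive <- runif(1) < 0.2
      mod <- if (use_repressive) "H3K27me3" else
        sample(ACTIVATING_MODALITIES, 1)
      gain <- (mem_dir[j] == "up") != use_repressive
      cls <- if (gain) "gain_maintained" else "loss_maintained"
      assign(key(mod, region), cls, envir = cls_env)
      link_rows[[length(link_rows) + 1]] <- data.frame(
        gene = g, modality = mod, region = region, locus_type = locus,
        direction = if (gain) "gain" else "loss")
    }
  }
  explanation_link <- if (length(link_rows) > 0) {
    do.call(rbind, link_rows)
  } else {
    data.frame(gene = character(0), modality = character(0),
               region = character(0), locus_type = character(0),
               direction = character(0))
  }
  ## 2) other planted trajectory classes on loci of null genes
  null_genes <- gene_truth$gene[gene_truth$class == "null"]
  null_loci <- layout$region[layout$gene_id %in% null_genes]
  n_extra <- sum(config$planted_regions)
  pool <- expand.grid(modality = MODALITIES, region = null_loci,
                      stringsAsFactors = FALSE)
  if (n_extra > nrow(pool)) stop("not enough null-gene loci for planting")
  extra <- pool[sample(nrow(pool), n_extra), , drop = FALSE]
  extra_cls <- rep(names(config$planted_regions),
                   times = config$planted_regions)
  for (i in seq_len(nrow(extra))) {
    k <- key(extra$modality[i], extra$region[i])
    if (!exists(k, envir = cls_env)) assign(k, extra_cls[i], envir = cls_env)
  }
  keys <- key(region_class$modality, region_class$region)
  planted <- vapply(keys, function(k)
    if (exists(k, envir = cls_env)) get(k, envir = cls_env) else "stable",
    character(1))
  region_class$class <- unname(planted)
  ## 3) counts
  n_rep <- config$n_replicates_per_condition
  sample_meta <- data.frame(
    sample = paste0(rep(config$region_conditions, each = n_rep), "_rep",
                    rep(seq_len(n_rep), length(config$region_conditions))),
    condition = rep(config$region_conditions, each = n_rep),
    replicate = rep(seq_len(n_rep), length(config$region_conditions)))
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  size <- if (config$region_nb_dispersion > 0) {
    1 / config$region_nb_dispersion
  } else Inf
  n_regions <- nrow(layout)
  counts <- list()
  for (mod in MODALITIES) {
    base <- exp(runif(n_regions, log(config$region_mean_range[1]),
                      log(config$region_mean_range[2])))
    cls <- region_class$class[region_class$modality == mod][
      match(layout$region,
            region_class$region[region_class$modality == mod])]
    mat <- matrix(0L, nrow = n_regions, ncol = nrow(sample_meta),
                  dimnames = list(layout$region, sample_meta$sample))
    lib <- rlnorm(nrow(sample_meta), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    for (s in seq_len(nrow(sample_meta))) {
      shift <- region_shift(cls, sample_meta$condition[s],
                            config$region_effect_log2fc)
      mu <- base * 2^shift * lib[s]
      mat[, s] <- rnbinom(n_regions, mu = mu, size = size)
    }
    counts[[mod]] <- mat
  }
  list(regions = layout, counts = counts, sample_meta = sample_meta,
       region_class = region_class, explanation_link = explanation_link)
}

## Two-state Markov chain sampled by alternating geometric run lengths;
## p01 = P(off -> on), p10 = P(on -> off).
markov_track <- function(n, p01, p10) {
  pi1 <- p01 / (p01 + p10)
  state <- runif(1) < pi1
  out <- logical(n)
  pos <- 1L
  ## generous batch of run lengths, refilled if exhausted
  while (pos <= n) {
    len <- 1L + rgeom(1, if (state) p10 else p01)
    end <- min(n, pos + len - 1L)
    out[pos:end] <- state
    pos <- end + 1L
    state <- !state
  }
  out
}

#' Simulate binary binned mark tracks and planted enhancer bins
#'
#' Tiles the genome in `bin_width` bins and, for each modality, simulates
#' a binary "marked" state as a two-state Markov chain (blocky tracks with
#' geometric run lengths). The planted enhancer bins are exactly the bins
#' with H3K4me1 = 1, H3K27ac = 1, ATAC = 1, H3K4me3 = 0 that do not
#' overlap a promoter window.
#'
#' @param config A [sim_config()].
#' @param promoters `GRanges` of promoter windows (see [make_promoters()]).
#' @return List with `bins` (`data.frame`: `chrom`, `start`, `end` and one
#'   0/1 column per modality) and `enhancer_bins` (the planted subset of
#'   `bins` rows, as a `data.frame` of intervals).
#' @export
simulate_binned_tracks <- function(config, promoters) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  bins_per_chrom <- config$chrom_length %/% config$bin_width
  chrom <- rep(paste0("chr", seq_len(config$n_chroms)),
               each = bins_per_chrom)
  start0 <- rep((seq_len(bins_per_chrom) - 1L) * config$bin_width,
                config$n_chroms)
  bins <- data.frame(chrom = chrom, start = start0,
                     end = start0 + config$bin_width)
  n <- nrow(bins)
  ## marked fractions ~0.17 (activating marks / ATAC) and ~0.10 (H3K27me3)
  params <- list(H3K4me3 = c(0.02, 0.10), H3K27me3 = c(0.01, 0.09),
                 H3K27ac = c(0.02, 0.10), H3K4me1 = c(0.02, 0.10),
                 ATAC = c(0.02, 0.10))
  for (mod in MODALITIES) {
    p <- params[[mod]]
    bins[[mod]] <- as.integer(markov_track(n, p[1], p[2]))
  }
  qual <- bins$H3K4me1 == 1 & bins$H3K27ac == 1 & bins$ATAC == 1 &
    bins$H3K4me3 == 0
  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))
  in_prom <- IRanges::overlapsAny(bin_gr, promoters, ignore.strand = TRUE)
  enh <- bins[qual & !in_prom, c("chrom", "start", "end")]
  rownames(enh) <- NULL
  list(bins = bins, enhancer_bins = enh)
}

#' Run the full synthetic-study generator
#'
#' Convenience wrapper producing annotation, single-nucleus counts, region
#' counts, binned tracks and the merged planted truth in one call.
#'
#' @param config A [sim_config()].
#' @return List with components `config`, `genes`, `sn` (counts,
#'   cell_meta, truth), `regions` (see [simulate_region_counts()]),
#'   `tracks` (see [simulate_binned_tracks()]) and `promoters`.
#' @export
simulate_study <- function(config = sim_config()) {
  genes <- simulate_gene_annotation(config)
  sn <- simulate_sn_counts(config, genes)
  regions <- simulate_region_counts(config, genes, gene_truth = sn$truth)
  genome <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  promoters <- make_promoters(genes, flank = 2000, genome = genome)
  tracks <- simulate_binned_tracks(config, promoters)
  set.seed(config$seed + 5L)
  bl_chrom <- sample(names(genome), 50, replace = TRUE)
  bl_start <- floor(runif(50, 0, genome[bl_chrom] - 5000))
  bl_len <- floor(runif(50, 1000, 5000))
  blacklist <- GenomicRanges::reduce(GenomicRanges::GRanges(
    bl_chrom, IRanges::IRanges(bl_start + 1, bl_start + bl_len)))
  list(config = config, genes = genes, sn = sn, regions = regions,
       tracks = tracks, promoters = promoters, genome = genome,
       blacklist = blacklist)
}
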