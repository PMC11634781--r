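## End-to-end driver: simulate a study (or accept one), run QC,
## normalization, DEG contrasts, retention and pattern classification,
## per-modality region differentials with the promoter/enhancer cut-off
## policies, trajectory classes, enhancer calling, region-gene linkage,
## the gene-epigenome map and the explanation scorers, and write every
## product as TSV/BED.

#' Run the full obesogenic-memory analysis on a (synthetic) study
#'
#' Contrasts follow the study design: obese vs control (H vs C, HH vs C),
#' weight loss vs age-matched control (HC vs CC, HHC vs CCC) and rebound
#' (HCH vs CCH), using whichever conditions the study contains. Promoter
#' region tests use the nominal-p policy (P < 0.01, |log2FC| > 1); enhancer
#' region tests the FDR policy (BH FDR < 0.05, |log2FC| > 1). DEG calling
#' uses the Wilcoxon rank-sum test with Bonferroni-adjusted P < 0.01 and
#' |log2FC| > 0.5.
#'
#' @param config A [sim_config()]; ignored when `study` is supplied.
#' @param study Optional pre-built study (output of [simulate_study()]).
#' @param outdir Optional directory; when given, all products are written
#'   as TSV/BED files.
#' @param explain_mode Explanation logic for the scorers
#'   (`"any_modality"` or `"direction_consistent"`; both are computed,
#'   this picks which fills the summary).
#' @return List with components `study`, `deg` (per contrast), `retention`,
#'   `patterns` (when all four arms exist), `region_diffs` (per modality:
#'   obese/wl tables), `trajectories`, `dispersion` (per modality),
#'   `linkage`, `enhancers` (rule-called from tracks), `map`,
#'   `explanation` (both modes), `rebound` (when HCH/CCH exist).
#' @export
run_memory_pipeline <- function(config = sim_config(), study = NULL,
                                outdir = NULL,
                                explain_mode = c("any_modality",
                                                 "direction_consistent")) {
  explain_mode <- match.arg(explain_mode)
  if (is.null(study)) study <- simulate_study(config)
  config <- study$config
  conds <- unique(study$sn$cell_meta$condition)

  ## --- single-nucleus arm -------------------------------------------------
  qc <- qc_filter_cells(study$sn$counts, study$sn$cell_meta,
                        min_features = config$qc_min_features,
                        max_features = config$qc_max_features,
                        max_umi = config$qc_max_umi)
  norm <- lognormalize(qc$counts)
  meta <- qc$cell_meta
  contrast_defs <- list(H = c("H", "C"), HC = c("HC", "CC"),
                        HH = c("HH", "C"), HHC = c("HHC", "CCC"),
                        HCH = c("HCH", "CCH"))
  deg <- list()
  for (nm in names(contrast_defs)) {
    pair <- contrast_defs[[nm]]
    if (all(pair %in% conds)) {
      deg[[nm]] <- wilcoxon_deg(norm,
                                meta$condition == pair[1],
                                meta$condition == pair[2])
    }
  }
  retention <- NULL
  if (!is.null(deg$H) && !is.null(deg$HC)) {
    retention <- classify_retention(deg$H, deg$HC, cell_type = "adipocyte")
  }
  patterns <- NULL
  if (all(c("H", "HC", "HH", "HHC") %in% names(deg))) {
    patterns <- classify_patterns(deg$H, deg$HC, deg$HH, deg$HHC)
  }

  ## --- region arm ---------------------------------------------------------
  layout <- study$regions$regions
  smeta <- study$regions$sample_meta
  is_prom <- layout$locus_type == "promoter"
  region_diffs <- list(); dispersion <- list(); trajectories <- list()
  have_region_arm <- all(c("H", "C", "HC", "CC") %in% smeta$condition)
  if (have_region_arm) {
    for (mod in names(study$regions$counts)) {
      cnt <- study$regions$counts[[mod]]
      phi <- estimate_common_dispersion(cnt, smeta$condition)
      dispersion[[mod]] <- phi
      diff_one <- function(a, b) {
        prom <- nb_exact_test(cnt[is_prom, , drop = FALSE],
                              smeta$condition, a, b, phi,
                              lfc_threshold = 1, alpha = 0.01,
                              alpha_on = "p")
        enh <- nb_exact_test(cnt[!is_prom, , drop = FALSE],
                             smeta$condition, a, b, phi,
                             lfc_threshold = 1, alpha = 0.05,
                             alpha_on = "fdr")
        rbind(prom, enh)
      }
      obese <- diff_one("H", "C")
      wl <- diff_one("HC", "CC")
      region_diffs[[mod]] <- list(obese = obese, wl = wl)
      trajectories[[mod]] <- classify_trajectory(obese, wl, modality = mod)
    }
  }

  ## --- linkage, map, explanation -----------------------------------------
  enh_rows <- layout[!is_prom, , drop = FALSE]
  enh_gr <- GenomicRanges::GRanges(
    enh_rows$chrom, IRanges::IRanges(enh_rows$start + 1L, enh_rows$end))
  S4Vectors::mcols(enh_gr)$name <- enh_rows$region
  linkage <- link_regions_to_genes(enh_gr, study$genes, max_dist = 20000)

  map <- NULL; explanation <- NULL; rebound <- NULL
  if (have_region_arm && !is.null(retention)) {
    ## promoter tables re-keyed by gene (promoter counts represent genes)
    rekey <- function(tab) {
      tab$feature <- sub("^prom_", "", tab$feature)
      tab
    }
    promoter_diffs <- lapply(region_diffs, function(d)
      list(obese = rekey(d$obese[grepl("^prom_", d$obese$feature), ]),
           wl = rekey(d$wl[grepl("^prom_", d$wl$feature), ])))
    enhancer_diffs <- lapply(region_diffs, function(d)
      list(obese = d$obese[!grepl("^prom_", d$obese$feature), ],
           wl = d$wl[!grepl("^prom_", d$wl$feature), ]))
    map <- build_gene_epigenome_map(promoter_diffs, enhancer_diffs,
                                    linkage,
                                    persistence = "obese_and_wl")
    explanation <- list(
      any_modality = explain_memory_degs(retention, map,
                                         mode = "any_modality"),
      direction_consistent = explain_memory_degs(
        retention, map, mode = "direction_consistent"))
    if (!is.null(deg$HCH)) {
      map_wl <- build_gene_epigenome_map(promoter_diffs, enhancer_diffs,
                                         linkage, persistence = "wl_only")
      rebound <- explain_rebound_degs(deg$HCH, deg$HC, retention, map_wl,
                                      mode = explain_mode)
    }
  }

  ## --- rule-based enhancers from binned tracks ----------------------------
  enhancers <- call_enhancers_by_rule(study$tracks$bins, study$promoters)

  result <- list(study = study, deg = deg, retention = retention,
                 patterns = patterns, region_diffs = region_diffs,
                 dispersion = dispersion, trajectories = trajectories,
                 linkage = linkage, enhancers = enhancers, map = map,
                 explanation = explanation, rebound = rebound)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  for (nm in names(result$deg)) {
    write_tsv(result$deg[[nm]], p(paste0("deg_", nm, ".tsv")))
  }
  if (!is.null(result$retention)) {
    write_tsv(result$retention, p("memory_calls.tsv"))
    write_tsv(retention_proportions(result$retention),
              p("retention_proportions.tsv"))
  }
  if (!is.null(result$patterns)) {
    write_tsv(result$patterns, p("pattern_calls.tsv"))
  }
  for (mod in names(result$region_diffs)) {
    write_tsv(result$region_diffs[[mod]]$obese,
              p(paste0("region_diff_", mod, "_obese.tsv")))
    write_tsv(result$region_diffs[[mod]]$wl,
              p(paste0("region_diff_", mod, "_wl.tsv")))
    write_tsv(result$trajectories[[mod]],
              p(paste0("trajectory_", mod, ".tsv")))
  }
  if (length(result$dispersion) > 0) {
    write_tsv(data.frame(modality = names(result$dispersion),
                         dispersion = unlist(result$dispersion)),
              p("dispersion.tsv"))
  }
  write_tsv(result$linkage, p("linkage.tsv"))
  write_bed(result$enhancers, p("enhancers_rule.bed"))
  if (!is.null(result$map)) write_tsv(result$map, p("gene_epigenome_map.tsv"))
  if (!is.null(result$explanation)) {
    write_tsv(result$explanation$any_modality$records,
              p("explanation_records.tsv"))
    fr <- rbind(
      cbind(mode = "any_modality",
            result$explanation$any_modality$fractions),
      cbind(mode = "direction_consistent",
            result$explanation$direction_consistent$fractions))
    write_tsv(fr, p("explanation_fractions.tsv"))
  }
  if (!is.null(result$rebound)) {
    write_tsv(result$rebound$records, p("rebound_records.tsv"))
    write_tsv(result$rebound$fractions, p("rebound_fractions.tsv"))
  }
  invisible(outdir)
}
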