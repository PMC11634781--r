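#' Rule-based enhancer calling from binned mark tracks
#'
#' Selects 200-bp (or any fixed-width) genome bins that are marked by
#' H3K4me1 and H3K27ac, open by ATAC, and not marked by H3K4me3; merges
#' runs of selected bins (gaps of up to `merge_gap` bins are bridged) into
#' intervals; and removes any interval overlapping (>= 1 bp) a promoter
#' window.
#'
#' @param bins `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open, genome-tiling) and logical/0-1 columns `H3K4me1`,
#'   `H3K27ac`, `ATAC`, `H3K4me3`.
#' @param promoters `GRanges` of promoter windows.
#' @param merge_gap Number of non-qualifying bins allowed inside a merged
#'   interval (default 0: only adjacent bins merge).
#' @return `GRanges` of enhancer intervals (no promoter overlap).
#' @export
call_enhancers_by_rule <- function(bins, promoters, merge_gap = 0) {
  need <- c("chrom", "start", "end", "H3K4me1", "H3K27ac", "ATAC", "H3K4me3")
  stopifnot(all(need %in% names(bins)), merge_gap >= 0)
  sel <- bins$H3K4me1 > 0 & bins$H3K27ac > 0 & bins$ATAC > 0 &
    !(bins$H3K4me3 > 0)
  if (!any(sel)) return(GenomicRanges::GRanges())
  hit <- bins[sel, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    hit$chrom, IRanges::IRanges(hit$start + 1L, hit$end))
  bin_width <- stats::median(bins$end - bins$start)
  merged <- GenomicRanges::reduce(
    gr, min.gapwidth = merge_gap * bin_width + 1L)
  keep <- !IRanges::overlapsAny(merged, promoters, ignore.strand = TRUE)
  merged[keep]
}

#' Trajectory classification of differential regions across obesity and
#' weight loss
#'
#' Combines per-region calls from the obese-vs-control and WL-vs-control
#' contrasts into trajectory classes: `(up, up)` gained and maintained
#' (a "new enhancer" when the modality is H3K4me1), `(up, ns)` gained then
#' lost, `(down, down)` lost and maintained, `(down, ns)` lost then
#' regained, `(ns, up)` / `(ns, down)` WL-only changes, `(ns, ns)` stable.
#' Direction reversals `(up, down)` / `(down, up)` are flagged as
#' `reversal` rather than forced into a class.
#'
#' @param diff_obese,diff_wl Differential-result `data.frame`s over the
#'   same region universe.
#' @param modality Optional label copied into the output.
#' @return `data.frame` with columns `region`, `modality`, `class` and
#'   logical `reversal`.
#' @export
classify_trajectory <- function(diff_obese, diff_wl,
                                modality = NA_character_) {
  check_diff_table(diff_obese); check_diff_table(diff_wl)
  if (!setequal(diff_obese$feature, diff_wl$feature) ||
      nrow(diff_obese) != nrow(diff_wl)) {
    stop("obese and WL contrasts cover different region universes")
  }
  ob <- diff_obese$call
  wl <- diff_wl$call[match(diff_obese$feature, diff_wl$feature)]
  key <- paste(ob, wl, sep = "|")
  rule <- c("up|up" = "gained_maintained", "up|ns" = "gained_lost",
            "down|down" = "lost_maintained", "down|ns" = "lost_regained",
            "ns|up" = "wl_only_gain", "ns|down" = "wl_only_loss",
            "ns|ns" = "stable", "up|down" = "reversal",
            "down|up" = "reversal")
  cls <- unname(rule[key])
  data.frame(region = diff_obese$feature, modality = modality,
             class = cls, reversal = cls == "reversal", row.names = NULL)
}

#' H3K27ac activity status of enhancers per condition
#'
#' An enhancer is active in a condition iff it overlaps (>= 1 bp) an
#' H3K27ac peak called in that condition.
#'
#' @param enhancers `GRanges` of enhancer intervals.
#' @param h3k27ac_peaks Named list of `GRanges`, one per condition.
#' @return `data.frame`: one row per enhancer, one logical column per
#'   condition, plus the enhancer identifier in `region`.
#' @export
acetylation_status <- function(enhancers, h3k27ac_peaks) {
  stopifnot(is.list(h3k27ac_peaks), length(h3k27ac_peaks) > 0)
  if (is.null(names(h3k27ac_peaks)) || any(!nzchar(names(h3k27ac_peaks)))) {
    stop("h3k27ac_peaks must be a named list (condition -> GRanges)")
  }
  out <- data.frame(region = region_names(enhancers))
  for (cond in names(h3k27ac_peaks)) {
    out[[cond]] <- IRanges::overlapsAny(
      enhancers, h3k27ac_peaks[[cond]], ignore.strand = TRUE)
  }
  out
}
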