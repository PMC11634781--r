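#' Classify obese-state DEGs into restored / memory / sign-flip
#'
#' Overlays a differential result from an obese-vs-control contrast with
#' the matching weight-loss-vs-control contrast. An obese DEG that is no
#' longer deregulated after weight loss is `restored`; one still deregulated
#' in the same direction is part of the transcriptional `memory`; direction
#' reversal is reported as `sign_flip`. Genes significant only in the
#' weight-loss contrast are reported with status `wl_only` and excluded
#' from retention denominators downstream.
#'
#' @param deg_obese,deg_wl Differential-result `data.frame`s (columns
#'   `feature`, `log2fc`, `p`, `p_adj`, `call`) over the same feature
#'   universe.
#' @param cell_type Optional label copied into the output.
#' @return `data.frame` with columns `gene`, `cell_type`, `direction`
#'   (`up`/`down`; obese direction, or WL direction for `wl_only` rows) and
#'   `status` (`restored`, `memory`, `sign_flip`, `wl_only`).
#' @export
classify_retention <- function(deg_obese, deg_wl, cell_type = NA_character_) {
  check_diff_table(deg_obese); check_diff_table(deg_wl)
  if (!setequal(deg_obese$feature, deg_wl$feature) ||
      nrow(deg_obese) != nrow(deg_wl)) {
    stop("obese and WL contrasts cover different feature universes")
  }
  wl_call <- deg_wl$call[match(deg_obese$feature, deg_wl$feature)]
  ob_call <- deg_obese$call
  is_deg <- ob_call != "ns"
  status <- character(nrow(deg_obese))
  status[is_deg & wl_call == "ns"] <- "restored"
  status[is_deg & wl_call == ob_call] <- "memory"
  status[is_deg & wl_call != "ns" & wl_call != ob_call] <- "sign_flip"
  wl_only <- !is_deg & wl_call != "ns"
  status[wl_only] <- "wl_only"
  keep <- status != ""
  data.frame(
    gene = deg_obese$feature[keep],
    cell_type = cell_type,
    direction = ifelse(wl_only[keep], wl_call[keep], ob_call[keep]),
    status = status[keep],
    row.names = NULL)
}

#' Proportion of retained (memory) transcriptional changes
#'
#' Per cell type and direction: `#memory / (#memory + #restored)`.
#' Sign-flip and WL-only calls never enter the ratio. Cell types with
#' fewer than `min_cells_per_group` cells in any donor/condition group are
#' excluded when `cell_counts` is supplied. A cell type/direction with no
#' obese DEGs yields `NA` (undefined), not 0.
#'
#' @param calls Output of [classify_retention()] (possibly several cell
#'   types row-bound together).
#' @param cell_counts Optional `data.frame` with columns `cell_type` and
#'   `n_cells` (one row per cell type per donor/condition group).
#' @param min_cells_per_group Minimum group size for a cell type to be
#'   reported (default 30).
#' @return `data.frame` with `cell_type`, `direction`, `n_memory`,
#'   `n_restored`, `proportion_retained`.
#' @export
retention_proportions <- function(calls, cell_counts = NULL,
                                  min_cells_per_group = 30) {
  stopifnot(all(c("gene", "cell_type", "direction", "status") %in%
                  names(calls)))
  cts <- unique(calls$cell_type)
  if (!is.null(cell_counts)) {
    bad <- unique(cell_counts$cell_type[
      cell_counts$n_cells < min_cells_per_group])
    cts <- setdiff(cts, bad)
  }
  out <- expand.grid(cell_type = cts, direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  out$n_memory <- integer(nrow(out)); out$n_restored <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    sub <- calls[calls$cell_type %in% out$cell_type[i] &
                   calls$direction == out$direction[i], , drop = FALSE]
    out$n_memory[i] <- sum(sub$status == "memory")
    out$n_restored[i] <- sum(sub$status == "restored")
  }
  denom <- out$n_memory + out$n_restored
  out$proportion_retained <- ifelse(denom > 0, out$n_memory / denom, NA_real_)
  out
}

#' Three weight-loss restoration patterns across both study arms
#'
#' Considers genes that are DEGs (same direction) in both obesity
#' time-point contrasts (H and HH vs controls) and classifies their
#' weight-loss behaviour: still deregulated after both WL arms
#' (`not_restored_both`), restored only after the short-obesity arm
#' (`restored_HC_only`), restored after both (`restored_both`), restored
#' only after the long-obesity arm (`restored_HHC_only`); any other
#' combination (including direction reversals) is `other`.
#'
#' @param deg_h,deg_hc,deg_hh,deg_hhc Differential-result `data.frame`s for
#'   the H, HC, HH and HHC contrasts against their respective controls,
#'   same feature universe.
#' @return `data.frame` with columns `gene`, `direction`, `pattern`.
#' @export
classify_patterns <- function(deg_h, deg_hc, deg_hh, deg_hhc) {
  tabs <- list(deg_h, deg_hc, deg_hh, deg_hhc)
  for (t in tabs) check_diff_table(t)
  feats <- deg_h$feature
  for (t in tabs[-1]) {
    if (!setequal(t$feature, feats)) {
      stop("all four contrasts must cover the same feature universe")
    }
  }
  call_of <- function(tab) tab$call[match(feats, tab$feature)]
  h <- call_of(deg_h); hc <- call_of(deg_hc)
  hh <- call_of(deg_hh); hhc <- call_of(deg_hhc)
  in_scope <- h != "ns" & h == hh
  res_hc <- hc == "ns"
  res_hhc <- hhc == "ns"
  mem_hc <- hc == h
  mem_hhc <- hhc == h
  pattern <- rep("other", length(feats))
  pattern[mem_hc & mem_hhc] <- "not_restored_both"
  pattern[res_hc & mem_hhc] <- "restored_HC_only"
  pattern[res_hc & res_hhc] <- "restored_both"
  pattern[mem_hc & res_hhc] <- "restored_HHC_only"
  data.frame(gene = feats[in_scope], direction = h[in_scope],
             pattern = pattern[in_scope], row.names = NULL)
}

check_diff_table <- function(tab) {
  need <- c("feature", "log2fc", "p", "p_adj", "call")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop("expected a differential-result data.frame with columns ",
         paste(need, collapse = ", "))
  }
  invisible(tab)
}
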