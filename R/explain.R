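## Modalities whose gain is expected to accompany upregulation; H3K27me3
## (polycomb-repressive) works in the opposite direction.
ACTIVATING_MODALITIES <- c("H3K4me3", "H3K27ac", "H3K4me1", "ATAC")
REPRESSIVE_MODALITIES <- c("H3K27me3")

#' Map genes to their persistent differential epigenetic entries
#'
#' For every gene, collects (modality, locus_type, direction) entries from
#' its promoter and from enhancers linked to it, keeping only entries that
#' are persistent: significant in the same direction in both the obese and
#' WL contrasts (`persistence = "obese_and_wl"`), or significant in the WL
#' contrast regardless of obesity-time status (`"wl_only"`, the reading
#' used for the rebound analysis).
#'
#' @param promoter_diffs Named list (modality -> list(obese = , wl = ) of
#'   differential-result `data.frame`s keyed by gene) for promoter-level
#'   counts; may be `NULL`.
#' @param enhancer_diffs Same structure keyed by region identifier; may be
#'   `NULL`.
#' @param linkage `data.frame` from [link_regions_to_genes()] mapping
#'   enhancer regions to genes. Required when `enhancer_diffs` is given.
#' @param persistence `"obese_and_wl"` (default) or `"wl_only"`.
#' @param modalities Modalities to include (default: all present).
#' @return `data.frame` with columns `gene`, `modality`, `locus_type`
#'   (`promoter`/`enhancer`), `direction` (`gain`/`loss`), `region`.
#' @export
build_gene_epigenome_map <- function(promoter_diffs = NULL,
                                     enhancer_diffs = NULL,
                                     linkage = NULL,
                                     persistence = c("obese_and_wl",
                                                     "wl_only"),
                                     modalities = NULL) {
  persistence <- match.arg(persistence)
  known <- c(ACTIVATING_MODALITIES, REPRESSIVE_MODALITIES)
  empty <- data.frame(gene = character(0), modality = character(0),
                      locus_type = character(0), direction = character(0),
                      region = character(0))
  out <- list(empty)
  persistent_calls <- function(pair) {
    if (!is.list(pair) || is.null(pair$obese) || is.null(pair$wl)) {
      stop("each modality needs both 'obese' and 'wl' differential tables")
    }
    check_diff_table(pair$obese); check_diff_table(pair$wl)
    wl_call <- pair$wl$call[match(pair$obese$feature, pair$wl$feature)]
    if (anyNA(wl_call)) stop("obese/wl feature universes differ")
    keep <- if (persistence == "obese_and_wl") {
      pair$obese$call != "ns" & pair$obese$call == wl_call
    } else {
      !is.na(wl_call) & wl_call != "ns"
    }
    data.frame(feature = pair$obese$feature[keep],
               direction = ifelse(
                 (if (persistence == "obese_and_wl") pair$obese$call[keep]
                  else wl_call[keep]) == "up", "gain", "loss"))
  }
  for (mod in names(promoter_diffs)) {
    if (!mod %in% known) stop("unknown modality: ", mod)
    if (!is.null(modalities) && !mod %in% modalities) next
    pc <- persistent_calls(promoter_diffs[[mod]])
    if (nrow(pc) > 0) {
      out[[length(out) + 1]] <- data.frame(
        gene = pc$feature, modality = mod, locus_type = "promoter",
        direction = pc$direction, region = pc$feature)
    }
  }
  if (!is.null(enhancer_diffs) && length(enhancer_diffs) > 0) {
    if (is.null(linkage)) stop("enhancer_diffs requires a linkage table")
    for (mod in names(enhancer_diffs)) {
      if (!mod %in% known) stop("unknown modality: ", mod)
      if (!is.null(modalities) && !mod %in% modalities) next
      pc <- persistent_calls(enhancer_diffs[[mod]])
      hit <- match(pc$feature, linkage$region)
      ok <- !is.na(hit)
      if (any(ok)) {
        out[[length(out) + 1]] <- data.frame(
          gene = linkage$gene_id[hit[ok]], modality = mod,
          locus_type = "enhancer", direction = pc$direction[ok],
          region = pc$feature[ok])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## TRUE for entries whose direction is consistent with the DEG direction:
## upregulation goes with gain of activating marks or loss of the
## repressive mark; downregulation mirrored.
entry_direction_consistent <- function(entry_modality, entry_direction,
                                       deg_direction) {
  activating <- entry_modality %in% ACTIVATING_MODALITIES
  ifelse(deg_direction == "up",
         (activating & entry_direction == "gain") |
           (!activating & entry_direction == "loss"),
         (activating & entry_direction == "loss") |
           (!activating & entry_direction == "gain"))
}

#' Fraction of memory DEGs explained by persistent epigenetic alterations
#'
#' A memory DEG is explained under `mode = "any_modality"` iff at least one
#' persistent differential entry exists at its promoter or a linked
#' enhancer; under `"direction_consistent"` the entry must also match the
#' DEG direction (gain of H3K4me3/H3K27ac/H3K4me1/ATAC or loss of H3K27me3
#' for upregulated genes; mirrored for downregulated).
#'
#' @param memory_calls Output of [classify_retention()]; only rows with
#'   `status == "memory"` are used.
#' @param map Output of [build_gene_epigenome_map()].
#' @param mode `"any_modality"` (default) or `"direction_consistent"`.
#' @return List with `records` (per-gene `data.frame`: `gene`, `direction`,
#'   `explained`, `n_supporting`) and `fractions` (`data.frame` per
#'   direction plus `overall`; `NA` when there are no memory DEGs).
#' @export
explain_memory_degs <- function(memory_calls, map,
                                mode = c("any_modality",
                                         "direction_consistent")) {
  mode <- match.arg(mode)
  mem <- memory_calls[memory_calls$status == "memory", , drop = FALSE]
  recs <- data.frame(gene = mem$gene, direction = mem$direction,
                     explained = logical(nrow(mem)),
                     n_supporting = integer(nrow(mem)))
  if (nrow(mem) > 0 && nrow(map) > 0) {
    for (i in seq_len(nrow(recs))) {
      ent <- map[map$gene == recs$gene[i], , drop = FALSE]
      if (mode == "direction_consistent" && nrow(ent) > 0) {
        ent <- ent[entry_direction_consistent(
          ent$modality, ent$direction, recs$direction[i]), , drop = FALSE]
      }
      recs$n_supporting[i] <- nrow(ent)
      recs$explained[i] <- nrow(ent) > 0
    }
  }
  frac_for <- function(sel) {
    if (sum(sel) == 0) NA_real_ else mean(recs$explained[sel])
  }
  fractions <- data.frame(
    direction = c("up", "down", "overall"),
    n = c(sum(recs$direction == "up"), sum(recs$direction == "down"),
          nrow(recs)),
    fraction_explained = c(frac_for(recs$direction == "up"),
                           frac_for(recs$direction == "down"),
                           frac_for(rep(TRUE, nrow(recs)))))
  list(records = recs, fractions = fractions)
}

#' Explain rebound DEGs by prior status, transcriptional memory, or
#' epigenetic memory
#'
#' For each DEG of the rebound contrast (re-exposed weight-loss mice vs
#' re-exposed controls, HCH vs CCH), three non-exclusive flags: (1)
#' `prior_deg_status` - the gene was a same-direction DEG at the WL (HC)
#' time point; (2) `transcriptional_memory` - the gene was classified as
#' memory at HC; (3) `epigenetic` - the gene carries a qualifying entry in
#' the epigenome map (any or direction-consistent, per `mode`).
#'
#' @param hch_degs Differential-result `data.frame` for the rebound
#'   contrast; only `up`/`down` rows are scored.
#' @param hc_degs Differential-result `data.frame` for the HC contrast.
#' @param memory_calls Output of [classify_retention()] for the HC arm.
#' @param map Output of [build_gene_epigenome_map()]; for the rebound
#'   question build it with `persistence = "wl_only"` (differentially
#'   marked at the WL time point).
#' @param mode `"any_modality"` (default) or `"direction_consistent"`.
#' @return List with `records` (per-DEG flags) and `fractions` (per source
#'   per direction).
#' @export
explain_rebound_degs <- function(hch_degs, hc_degs, memory_calls, map,
                                 mode = c("any_modality",
                                          "direction_consistent")) {
  mode <- match.arg(mode)
  check_diff_table(hch_degs); check_diff_table(hc_degs)
  deg <- hch_degs[hch_degs$call != "ns", , drop = FALSE]
  hc_call <- hc_degs$call[match(deg$feature, hc_degs$feature)]
  mem_genes <- memory_calls$gene[memory_calls$status == "memory"]
  mem_dir <- memory_calls$direction[memory_calls$status == "memory"]
  recs <- data.frame(gene = deg$feature, direction = deg$call,
                     prior_deg_status = !is.na(hc_call) &
                       hc_call == deg$call,
                     transcriptional_memory = FALSE, epigenetic = FALSE)
  m <- match(recs$gene, mem_genes)
  recs$transcriptional_memory <- !is.na(m) & mem_dir[m] == recs$direction
  if (nrow(map) > 0) {
    for (i in seq_len(nrow(recs))) {
      ent <- map[map$gene == recs$gene[i], , drop = FALSE]
      if (mode == "direction_consistent" && nrow(ent) > 0) {
        ent <- ent[entry_direction_consistent(
          ent$modality, ent$direction, recs$direction[i]), , drop = FALSE]
      }
      recs$epigenetic[i] <- nrow(ent) > 0
    }
  }
  frac <- function(flag, dir) {
    sel <- recs$direction == dir
    if (sum(sel) == 0) NA_real_ else mean(recs[[flag]][sel])
  }
  fractions <- expand.grid(
    source = c("prior_deg_status", "transcriptional_memory", "epigenetic"),
    direction = c("up", "down"), stringsAsFactors = FALSE)
  fractions$fraction <- mapply(frac, fractions$source, fractions$direction)
  fractions$n <- ifelse(fractions$direction == "up",
                        sum(recs$direction == "up"),
                        sum(recs$direction == "down"))
  list(records = recs, fractions = fractions)
}
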