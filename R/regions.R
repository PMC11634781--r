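#' @import GenomicRanges
#' @importFrom IRanges IRanges overlapsAny pintersect
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom methods is
NULL

## Coordinates: GRanges (1-based, closed) in memory; BED (0-based,
## half-open) on disk. Conversion happens only in read_bed()/write_bed().

#' Read a BED3/BED6 file into a GRanges
#'
#' Parses the BED dialect used throughout the package: tab-separated,
#' 0-based half-open intervals, three or six columns. `track`, `browser`
#' and `#` comment lines are skipped with a warning. Malformed lines
#' (fewer than 3 fields, non-numeric or inverted coordinates) raise an
#' error naming the offending line number.
#'
#' @param path Path to the BED file.
#' @param genome Optional named vector of chromosome lengths used to set
#'   `seqlengths` on the result.
#' @return A `GRanges`, with `name`, `score` and strand populated when six
#'   columns are present.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) seqlengths(gr) <- genome
    return(gr)
  }
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  if (any(skip & nzchar(lines))) {
    warning(sum(skip & nzchar(lines)), " header/track line(s) skipped in ", path)
  }
  keep_idx <- which(!skip)
  if (length(keep_idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(genome)) seqlengths(gr) <- genome
    return(gr)
  }
  fields <- strsplit(lines[keep_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- keep_idx[which(nf < 3L)[1L]]
    stop("malformed BED line ", bad, " in ", path, ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
  if (length(bad) > 0L) {
    stop("malformed BED line ", keep_idx[bad[1L]], " in ", path,
         ": need 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (all(nf >= 6L)) {
    mcols(gr)$name <- vapply(fields, `[[`, character(1), 4L)
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1), 5L)))
    strand_chr <- vapply(fields, `[[`, character(1), 6L)
    strand_chr[!strand_chr %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- strand_chr
  } else if (any(nf >= 4L)) {
    nm <- rep(NA_character_, length(gr))
    has4 <- nf >= 4L
    nm[has4] <- vapply(fields[has4], `[[`, character(1), 4L)
    mcols(gr)$name <- nm
  }
  if (!is.null(genome)) seqlengths(gr) <- genome[seqlevels(gr)]
  gr
}

#' Write a GRanges to a BED file
#'
#' Emits BED6 when the input carries `name` metadata or explicit strand,
#' BED3 otherwise. Coordinates are converted back to 0-based half-open.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(gr) == 0L) return(invisible(path))
  chrom <- as.character(seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  str_chr <- as.character(GenomicRanges::strand(gr))
  has_meta <- !is.null(mcols(gr)$name) || any(str_chr != "*")
  if (has_meta) {
    nm <- if (is.null(mcols(gr)$name)) rep(".", length(gr)) else
      ifelse(is.na(mcols(gr)$name), ".", mcols(gr)$name)
    sc <- if (is.null(mcols(gr)$score)) rep(0, length(gr)) else
      ifelse(is.na(mcols(gr)$score), 0, mcols(gr)$score)
    str_chr[str_chr == "*"] <- "."
    writeLines(paste(chrom, start0, end0, nm, sc, str_chr, sep = "\t"), con)
  } else {
    writeLines(paste(chrom, start0, end0, sep = "\t"), con)
  }
  invisible(path)
}

#' Promoter windows around strand-aware TSSs
#'
#' The promoter of a gene is the window of `flank` bp on either side of its
#' transcription start site: for a + strand gene the TSS is the leftmost
#' base, for a - strand gene the rightmost. Windows are clipped to
#' chromosome bounds when `genome` is supplied.
#'
#' @param genes A gene-model `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param flank Half-width of the window in bp (default 2000, i.e. a
#'   4,000-bp window).
#' @param genome Optional named vector of chromosome lengths for clipping.
#' @return A `GRanges` with one interval per gene; `name` holds `gene_id`.
#' @export
make_promoters <- function(genes, flank = 2000, genome = NULL) {
  stopifnot(is.data.frame(genes), flank > 0)
  tss0 <- gene_tss(genes)
  start0 <- pmax(0, tss0 - flank)
  end0 <- tss0 + flank
  if (!is.null(genome)) {
    lim <- genome[genes$chrom]
    end0 <- pmin(end0, lim)
  }
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start0 + 1, end0),
    strand = genes$strand)
  mcols(gr)$name <- genes$gene_id
  if (!is.null(genome)) seqlengths(gr) <- genome[seqlevels(gr)]
  gr
}

#' Strand-aware TSS positions (0-based) for a gene-model table
#' @param genes Gene-model `data.frame` (see [make_promoters()]).
#' @return Integer vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Total base-pair overlap between two region sets
#'
#' Both sets are merged internally, so duplicated or overlapping intervals
#' within a set are not double counted. The statistic is symmetric.
#'
#' @param a,b `GRanges`.
#' @param per_pair If `TRUE`, also return a table of per-pair overlaps
#'   between the original (unmerged) intervals.
#' @return Total overlap in bp, or a list with `total` and `pairs` when
#'   `per_pair = TRUE`.
#' @export
overlap_bp <- function(a, b, per_pair = FALSE) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  am <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  bm <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(am, bm, ignore.strand = TRUE)
  total <- sum(as.numeric(GenomicRanges::width(ov)))
  if (!per_pair) return(total)
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  pw <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(a)[queryHits(hits)],
    GenomicRanges::ranges(b)[subjectHits(hits)]))
  list(total = total,
       pairs = data.frame(a_index = queryHits(hits),
                          b_index = subjectHits(hits),
                          overlap_bp = pw))
}

#' Fold enrichment of one region set in another
#'
#' Computes `overlap_bp(peaks, feature) * genome_size /
#' (bp(peaks) * bp(feature))`, the ratio of observed overlap to the overlap
#' expected if both sets were placed uniformly at random on the genome.
#' Values above 1 indicate enrichment. Symmetric in its two region
#' arguments.
#'
#' @param peaks,feature `GRanges`; both must cover at least 1 bp.
#' @param genome_size Total genome length in bp.
#' @return A single numeric fold enrichment.
#' @export
fold_enrichment <- function(peaks, feature, genome_size) {
  stopifnot(genome_size > 0)
  bp_peaks <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(peaks, ignore.strand = TRUE))))
  bp_feat <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(feature, ignore.strand = TRUE))))
  if (bp_peaks == 0 || bp_feat == 0) {
    stop("fold_enrichment undefined for empty peak or feature set")
  }
  overlap_bp(peaks, feature) * genome_size / (bp_peaks * bp_feat)
}

#' Remove peaks overlapping a blacklist
#'
#' Any peak sharing at least 1 bp with any blacklist interval is dropped.
#'
#' @param peaks,blacklist `GRanges`.
#' @return The retained subset of `peaks`, original order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  stopifnot(is(peaks, "GRanges"), is(blacklist, "GRanges"))
  if (length(blacklist) == 0L) return(peaks)
  hit <- IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)
  peaks[!hit]
}

#' Merge region sets into a union peak list
#'
#' @param sets A list of `GRanges` (or a single `GRanges`).
#' @return Merged `GRanges`: no two output intervals overlap or abut.
#' @export
union_regions <- function(sets) {
  if (is(sets, "GRanges")) sets <- list(sets)
  stopifnot(length(sets) > 0, all(vapply(sets, is, logical(1), "GRanges")))
  all_gr <- suppressWarnings(do.call(c, lapply(sets, function(g) {
    mcols(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  })))
  GenomicRanges::reduce(all_gr, ignore.strand = TRUE)
}

#' Link regions to their closest gene within a distance cut-off
#'
#' A region's distance to a gene is 0 when it overlaps the gene body,
#' otherwise the smaller of the edge-to-edge gap to the gene body and the
#' gap to the TSS. Each region is assigned to the gene with minimal
#' distance if that distance is at most `max_dist`; ties break to the
#' lexicographically smallest `gene_id`. Regions farther than `max_dist`
#' from every gene are omitted.
#'
#' @param regions `GRanges`; `name` metadata (if present) is carried
#'   through as the region identifier, otherwise `chrom:start-end` labels
#'   are generated.
#' @param genes Gene-model `data.frame` (see [make_promoters()]).
#' @param max_dist Maximum linking distance in bp (default 20000).
#' @return `data.frame` with columns `region`, `gene_id`, `distance`.
#' @export
link_regions_to_genes <- function(regions, genes, max_dist = 20000) {
  stopifnot(is(regions, "GRanges"), is.data.frame(genes), max_dist >= 0)
  region_ids <- region_names(regions)
  if (length(regions) == 0L || nrow(genes) == 0L) {
    return(data.frame(region = character(0), gene_id = character(0),
                      distance = numeric(0)))
  }
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  tss0 <- gene_tss(genes)
  tss_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(tss0 + 1L, tss0 + 1L))
  ## distance() returns the gap (0 when overlapping/adjacent-with-overlap);
  ## evaluate every region x gene pair on the same chromosome.
  res_region <- character(0); res_gene <- character(0); res_dist <- numeric(0)
  for (ch in unique(as.character(seqnames(regions)))) {
    ridx <- which(as.character(seqnames(regions)) == ch)
    gidx <- which(genes$chrom == ch)
    if (length(gidx) == 0L) next
    r_start <- GenomicRanges::start(regions)[ridx]
    r_end <- GenomicRanges::end(regions)[ridx]
    g_start <- GenomicRanges::start(body_gr)[gidx]
    g_end <- GenomicRanges::end(body_gr)[gidx]
    t_pos <- GenomicRanges::start(tss_gr)[gidx]
    for (k in seq_along(ridx)) {
      ## gap = number of intervening bases; 0 when overlapping or abutting
      gap_body <- pmax(0, pmax(g_start - r_end[k], r_start[k] - g_end) - 1L)
      gap_tss <- pmax(0, pmax(t_pos - r_end[k], r_start[k] - t_pos) - 1L)
      d <- pmin(gap_body, gap_tss)
      ok <- which(d <= max_dist)
      if (length(ok) == 0L) next
      dmin <- min(d[ok])
      cand <- gidx[ok[d[ok] == dmin]]
      best <- cand[order(genes$gene_id[cand])][1L]
      res_region <- c(res_region, region_ids[ridx[k]])
      res_gene <- c(res_gene, genes$gene_id[best])
      res_dist <- c(res_dist, dmin)
    }
  }
  data.frame(region = res_region, gene_id = res_gene, distance = res_dist)
}

## Stable region identifiers: explicit names when present, else coordinates
## in BED convention.
region_names <- function(gr) {
  nm <- mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) {
    coord <- paste0(as.character(seqnames(gr)), ":",
                    GenomicRanges::start(gr) - 1L, "-",
                    GenomicRanges::end(gr))
    if (is.null(nm)) return(coord)
    nm[is.na(nm)] <- coord[is.na(nm)]
  }
  nm
}

#' Read a two-column chrom-sizes TSV
#' @param path Path to a headerless TSV with columns chrom and size.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}
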