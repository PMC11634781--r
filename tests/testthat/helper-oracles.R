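## Independent oracles and tiny fixture builders shared across test files.

## --- per-base-pair bitmap oracle for interval arithmetic -----------------
## Genomes are small (<= 1e5 bp); a logical vector per chromosome is the
## ground truth every interval operation must agree with.

gr_to_bitmap <- function(gr, genome) {
  bm <- lapply(genome, function(len) logical(len))
  if (length(gr) > 0) {
    chrom <- as.character(GenomeInfoDb::seqnames(gr))
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) bm[[chrom[i]]][s[i]:e[i]] <- TRUE
  }
  bm
}

bitmap_overlap_bp <- function(a, b, genome) {
  ba <- gr_to_bitmap(a, genome)
  bb <- gr_to_bitmap(b, genome)
  sum(vapply(names(genome), function(ch) sum(ba[[ch]] & bb[[ch]]),
             numeric(1)))
}

bitmap_to_gr <- function(bm) {
  out <- list()
  for (ch in names(bm)) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(starts[keep], ends[keep]))
    }
  }
  if (length(out) == 0) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))
}

bitmap_union <- function(sets, genome) {
  bm <- lapply(genome, function(len) logical(len))
  for (gr in sets) {
    b <- gr_to_bitmap(gr, genome)
    for (ch in names(genome)) bm[[ch]] <- bm[[ch]] | b[[ch]]
  }
  bitmap_to_gr(bm)
}

bitmap_filter_blacklist <- function(peaks, blacklist, genome) {
  bb <- gr_to_bitmap(blacklist, genome)
  keep <- vapply(seq_along(peaks), function(i) {
    ch <- as.character(GenomeInfoDb::seqnames(peaks)[i])
    !any(bb[[ch]][GenomicRanges::start(peaks)[i]:
                    GenomicRanges::end(peaks)[i]])
  }, logical(1))
  peaks[keep]
}

## canonical (chrom, start, end) table for order-insensitive comparison
gr_key <- function(gr) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  df <- df[order(df$chrom, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

random_granges <- function(n, genome, max_width = 2000) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- unname(genome[chrom])
  w <- sample.int(max_width, n, replace = TRUE)
  s <- floor(runif(n, 1, len - w))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1))
}

## --- exhaustive permutation oracle for the rank-sum test -----------------
## Enumerates every assignment of the pooled observations to group A and
## computes the two-sided p as twice the smaller tail of the rank-sum
## distribution (capped at 1), the same convention the package states.

perm_wilcox_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  combos <- utils::combn(length(r), nx)
  sums <- colSums(matrix(r[combos], nrow = nx))
  w <- sum(r[seq_len(nx)])
  tol <- 1e-8
  min(1, 2 * min(mean(sums <= w + tol), mean(sums >= w - tol)))
}

## --- brute-force multiple-testing definitions ----------------------------

brute_bonferroni <- function(p) pmin(1, length(p) * p)

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

## --- tiny builders -------------------------------------------------------

diff_table <- function(feature, call,
                       log2fc = ifelse(call == "up", 2,
                                       ifelse(call == "down", -2, 0)),
                       p = ifelse(call == "ns", 0.5, 1e-6)) {
  data.frame(feature = feature, log2fc = log2fc, p = p, p_adj = p,
             call = call)
}

toy_sim_config <- function(...) {
  sim_config(n_genes = 150, n_chroms = 1, chrom_length = 150 * 40000,
             n_cells_per_condition = 50,
             conditions = c("C", "CC", "H", "HC"),
             planted_genes = c(restored_up = 8, restored_down = 8,
                               memory_up = 8, memory_down = 8),
             planted_regions = c(gain_maintained = 4, gain_lost = 4,
                                 loss_maintained = 4, loss_regained = 4,
                                 wl_only = 4),
             qc_min_features = 10, seed = 101, ...)
}
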