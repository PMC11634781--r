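#' @importFrom utils read.table write.table
NULL

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write a count matrix as MTX plus row/column TSVs
#'
#' @param mat Matrix (dense or sparse) with dimnames.
#' @param prefix File prefix; writes `<prefix>.mtx`, `<prefix>_rows.tsv`,
#'   `<prefix>_cols.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_count_matrix <- function(mat, prefix) {
  sp <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  write_tsv(data.frame(id = rownames(mat)), paste0(prefix, "_rows.tsv"))
  write_tsv(data.frame(id = colnames(mat)), paste0(prefix, "_cols.tsv"))
  invisible(paste0(prefix, c(".mtx", "_rows.tsv", "_cols.tsv")))
}

#' Read a count matrix written by [write_count_matrix()]
#' @param prefix File prefix used at write time.
#' @return Sparse `dgCMatrix` with dimnames restored.
#' @export
read_count_matrix <- function(prefix) {
  mat <- methods::as(methods::as(Matrix::readMM(paste0(prefix, ".mtx")),
                                 "CsparseMatrix"), "generalMatrix")
  rownames(mat) <- read_tsv(paste0(prefix, "_rows.tsv"))$id
  colnames(mat) <- read_tsv(paste0(prefix, "_cols.tsv"))$id
  mat
}

#' Write a synthetic study to a fixture directory
#'
#' Emits the full bundle in plain-text interchange formats: gene models and
#' chrom sizes (TSV), single-nucleus counts (MTX + row/col TSVs), cell
#' metadata and planted gene truth (TSV), region layout / promoters /
#' blacklist / planted enhancer bins (BED), per-modality region counts and
#' sample metadata (TSV), binned mark tracks (TSV), region classes and
#' explanation links (TSV). Everything round-trips through the package
#' readers.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture_bundle <- function(study, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  p <- function(...) file.path(dir, ...)
  write_tsv(study$genes, p("genes.tsv"))
  write_tsv(data.frame(chrom = names(study$genome),
                       size = unname(study$genome)),
            p("chrom_sizes.tsv"))
  write_count_matrix(study$sn$counts, p("sn_counts"))
  write_tsv(study$sn$cell_meta, p("cell_meta.tsv"))
  write_tsv(study$sn$truth, p("gene_truth.tsv"))
  layout <- study$regions$regions
  layout_gr <- GenomicRanges::GRanges(
    layout$chrom, IRanges::IRanges(layout$start + 1L, layout$end))
  S4Vectors::mcols(layout_gr)$name <- layout$region
  write_bed(layout_gr, p("regions.bed"))
  write_bed(study$promoters, p("promoters.bed"))
  if (!is.null(study$blacklist)) write_bed(study$blacklist,
                                           p("blacklist.bed"))
  for (mod in names(study$regions$counts)) {
    write_tsv(data.frame(region = rownames(study$regions$counts[[mod]]),
                         study$regions$counts[[mod]],
                         check.names = FALSE),
              p(paste0("region_counts_", mod, ".tsv")))
  }
  write_tsv(study$regions$sample_meta, p("sample_meta.tsv"))
  write_tsv(study$regions$region_class, p("region_class.tsv"))
  write_tsv(study$regions$explanation_link, p("explanation_link.tsv"))
  write_tsv(study$tracks$bins, p("binned_tracks.tsv"))
  enh <- study$tracks$enhancer_bins
  if (nrow(enh) > 0) {
    enh_gr <- GenomicRanges::GRanges(
      enh$chrom, IRanges::IRanges(enh$start + 1L, enh$end))
    write_bed(enh_gr, p("enhancer_bins.bed"))
  } else {
    file.create(p("enhancer_bins.bed"))
  }
  invisible(dir)
}

#' Read back a fixture bundle written by [write_fixture_bundle()]
#' @param dir Fixture directory.
#' @return List mirroring the writable parts of a study object.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  genome_df <- read_tsv(p("chrom_sizes.tsv"))
  genome <- stats::setNames(genome_df$size, genome_df$chrom)
  counts <- list()
  for (f in list.files(dir, pattern = "^region_counts_.*\\.tsv$")) {
    mod <- sub("^region_counts_(.*)\\.tsv$", "\\1", f)
    df <- read_tsv(p(f))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$region
    counts[[mod]] <- m
  }
  list(
    genes = read_tsv(p("genes.tsv")),
    genome = genome,
    sn = list(counts = read_count_matrix(p("sn_counts")),
              cell_meta = read_tsv(p("cell_meta.tsv")),
              truth = read_tsv(p("gene_truth.tsv"))),
    regions = list(counts = counts,
                   sample_meta = read_tsv(p("sample_meta.tsv")),
                   region_class = read_tsv(p("region_class.tsv")),
                   explanation_link = read_tsv(p("explanation_link.tsv"))),
    tracks = list(bins = read_tsv(p("binned_tracks.tsv"))),
    promoters = read_bed(p("promoters.bed")),
    region_layout = read_bed(p("regions.bed")))
}
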