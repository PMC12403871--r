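# Library normalization and replicate-agreement statistics.

#' Median-of-ratios size factors
#'
#' The library-wise scaling factors of the median-of-ratios scheme: each
#' library's factor is the median, over genes with all-positive counts, of
#' the ratio of that library's count to the gene's geometric mean across
#' libraries.
#'
#' @param counts genes x libraries non-negative count matrix.
#' @return positive numeric vector of per-library factors (named when the
#'   matrix has column names).
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' size_factors(m) # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 libraries")
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in all libraries")
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  f <- apply(sub / geo, 2L, stats::median)
  stopifnot(all(f > 0))
  f
}

#' Reads per kilobase per million (RPKM)
#'
#' @param count gene read count(s).
#' @param gene_length gene length(s), nt (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return numeric RPKM value(s); linear in `count`.
#' @examples
#' rpkm(100, 1000, 1e6) # 100
#' @export
rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / (gene_length / 1e3) / (library_size / 1e6)
}

#' Pearson correlation between replicate end-count profiles
#'
#' Computed over the union of nonzero positions of the two profiles, with
#' zeros filled in where one replicate has no counts.
#'
#' @param a,b [end_profile()]s on the same contig and strand.
#' @param log1p correlate log1p-transformed counts instead of raw counts.
#' @return Pearson r in [-1, 1].
#' @export
replicate_correlation <- function(a, b, log1p = FALSE) {
  stopifnot(inherits(a, "end_profile"), inherits(b, "end_profile"))
  if (a$contig != b$contig || a$strand != b$strand) {
    stop("profiles must share contig and strand")
  }
  u <- sort(union(a$pos, b$pos))
  if (length(u) < 2L) stop("need at least 2 nonzero positions in the union")
  x <- profile_at(a, u); y <- profile_at(b, u)
  if (log1p) { x <- log1p(x); y <- log1p(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a profile is constant over the union")
  }
  stats::cor(x, y)
}
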