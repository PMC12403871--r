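# TEP calling and classification from Term-seq 3'-end profiles.
#
# A transcript 3'-end position (TEP) is a position whose 3'-end count
# clears a height threshold and is the local maximum of its neighbourhood
# (ties kept at the 3'-most position). Merged TEPs are classified into
# primary (P), secondary (S), cis-regulatory (C, inside a mapped 5'-UTR),
# antisense (A) and intergenic (N) categories.

#' Call TEP candidates from a Term-seq 3'-end profile
#'
#' @param termseq an [end_profile()] of 3'-end counts.
#' @param min_height minimum count (> 0).
#' @param local_window half-width of the local-maximum filter, nt; ties are
#'   kept at the 3'-most position.
#' @return data.frame with `pos`, `strand`, `height`.
#' @export
call_tep <- function(termseq, min_height = 10, local_window = 2L) {
  stopifnot(inherits(termseq, "end_profile"))
  if (min_height <= 0) stop("min_height must be > 0")
  strand <- termseq$strand
  cand <- termseq$pos[termseq$count >= min_height]
  if (!length(cand)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      height = numeric(0)))
  }
  h <- profile_at(termseq, cand)
  is_max <- vapply(seq_along(cand), function(i) {
    p <- cand[i]
    nb <- setdiff(p + (-local_window):local_window, p)
    nc <- profile_at(termseq, nb)
    if (any(nc > h[i])) return(FALSE)
    ties <- nb[nc == h[i]]
    # keep the 3'-most of a tie: reject p if a tie is more 3'
    !any(vapply(ties, function(q) .more_5p(p, q, strand), logical(1)))
  }, logical(1))
  data.frame(pos = cand[is_max], strand = strand, height = h[is_max])
}

#' Classify merged TEPs against the annotation and mapped 5'-UTRs
#'
#' For each gene, same-strand sites within `downstream_window` nt downstream
#' of its 3'-end compete: the highest becomes the primary (P) TEP, the rest
#' secondary (S). Remaining sites falling inside a primary-TSS-derived
#' 5'-UTR on the sense strand are cis-regulatory (C); sites inside a gene
#' body on the opposite strand are antisense (A); the rest intergenic (N).
#' Precedence P/S > C > A > N.
#'
#' @param sites merged TEP data.frame (`pos`, `strand`, `height`, ...).
#' @param annotation a `genome_annotation`.
#' @param tss_records classified TSS records with `utr5` (for the C class);
#'   may be NULL, in which case no C TEPs can be assigned.
#' @param downstream_window nt downstream of a gene 3'-end searched for its
#'   TEP.
#' @return sites with `category` (P/S/C/A/N), `gene`, `utr3` (P/S only)
#'   columns added.
#' @export
classify_tep <- function(sites, annotation, tss_records = NULL,
                         downstream_window = 300L) {
  g <- .gene_frame(annotation)
  n <- nrow(sites)
  category <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  utr3 <- rep(NA_integer_, n)

  assigned_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- sites$pos[i]; st <- sites$strand[i]
    cand <- g[g$strand == st, , drop = FALSE]
    d <- ifelse(cand$strand == "+", p - cand$end3, cand$end3 - p - 1L)
    hit <- which(d >= 1L & d <= downstream_window)
    if (length(hit)) {
      dd <- d[hit]
      best <- hit[dd == min(dd)]
      best <- best[order(cand$gene_id[best])][1L]
      assigned_gene[i] <- cand$gene_id[best]
      utr3[i] <- d[best]
    }
  }
  for (gid in unique(stats::na.omit(assigned_gene))) {
    idx <- which(assigned_gene == gid)
    hmax <- max(sites$height[idx])
    strand <- sites$strand[idx][1L]
    winners <- idx[sites$height[idx] == hmax]
    prim <- if (strand == "+") winners[which.max(sites$pos[winners])]
            else winners[which.min(sites$pos[winners])]
    category[prim] <- "P"
    category[setdiff(idx, prim)] <- "S"
    gene[idx] <- gid
  }
  # 5'-UTR intervals of primary TSSs, on the sense strand
  utr_iv <- NULL
  if (!is.null(tss_records) && nrow(tss_records)) {
    pr <- tss_records[tss_records$category == "P" &
                        !is.na(tss_records$utr5) & tss_records$utr5 > 0L, ,
                      drop = FALSE]
    if (nrow(pr)) {
      lo <- ifelse(pr$strand == "+", pr$pos, pr$pos - pr$utr5 + 1L)
      hi <- ifelse(pr$strand == "+", pr$pos + pr$utr5 - 1L, pr$pos)
      utr_iv <- data.frame(lo = lo, hi = hi, strand = pr$strand)
    }
  }
  for (i in which(is.na(category))) {
    p <- sites$pos[i]; st <- sites$strand[i]
    if (!is.null(utr_iv) &&
        any(utr_iv$strand == st & utr_iv$lo <= p & p <= utr_iv$hi)) {
      category[i] <- "C"; next
    }
    anti <- g[g$strand != st & g$start <= p & p < g$end, , drop = FALSE]
    category[i] <- if (nrow(anti)) "A" else "N"
  }
  sites$category <- category
  sites$gene <- gene
  sites$utr3 <- ifelse(category == "P" | category == "S", utr3, NA_integer_)
  sites
}

#' 3'-UTR length summary for primary TEPs
#'
#' @param records classified TEP data.frame with `utr3`.
#' @return list(`records`, `summary`) where summary holds the median, the
#'   modal 10-nt bin (bins [0,9], [10,19], ...), the fraction of short
#'   3'-UTRs (< 20 nt), and the full histogram.
#' @export
utr3_lengths <- function(records) {
  u <- records$utr3[records$category == "P" & !is.na(records$utr3)]
  if (any(u < 0L)) stop("negative 3'-UTR length (classification bug)")
  summary <- if (length(u)) {
    h <- table(cut(u, breaks = seq(0, max(u) + 10, 10), right = FALSE))
    modal <- names(h)[which.max(h)]
    list(median = stats::median(u), modal_bin = modal,
         fraction_short = mean(u < 20), histogram = h)
  } else {
    list(median = NA_real_, modal_bin = NA_character_,
         fraction_short = NA_real_, histogram = NULL)
  }
  list(records = records, summary = summary)
}
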