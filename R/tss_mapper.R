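# TSS calling and classification from dRNA-seq 5'-end profiles.
#
# A transcription start site is a position whose 5'-end count in the
# TEX-treated (processed-transcript-depleted) library clears a height
# threshold, is enriched over the untreated library, and is the local
# maximum of its +/- 2 nt neighbourhood. Sites called per condition are
# merged within +/- 5 nt and classified against the gene annotation into
# primary (P), secondary (S), internal (I), antisense (A) and intergenic
# (N) categories.

.is_upstream_5p <- function(strand) strand == "+"

# strand-aware "more 5'" comparison: on + smaller positions are 5'
.more_5p <- function(p, q, strand) if (strand == "+") p < q else p > q

#' Call TSS candidates from an enriched/unenriched dRNA-seq profile pair
#'
#' A position is a candidate iff its enriched count is at least
#' `min_height`, the pseudocounted ratio
#' (enriched + a)/(unenriched + a) with a = `pseudocount` is at least
#' `min_enrichment`, and the enriched count is the maximum within +/- 2 nt
#' (ties kept at the 5'-most position).
#'
#' @param enriched,unenriched [end_profile()]s on the same contig/strand.
#' @param min_height minimum enriched count (> 0).
#' @param min_enrichment minimum enrichment ratio (>= 1).
#' @param pseudocount added to both counts before the ratio.
#' @param local_window half-width of the local-maximum filter, nt.
#' @return data.frame with `pos`, `strand`, `height`, `enrichment`.
#' @export
call_tss <- function(enriched, unenriched, min_height = 10,
                     min_enrichment = 2, pseudocount = 1, local_window = 2L) {
  stopifnot(inherits(enriched, "end_profile"),
            inherits(unenriched, "end_profile"))
  if (enriched$contig != unenriched$contig ||
      enriched$strand != unenriched$strand) {
    stop("enriched/unenriched profiles must share contig and strand")
  }
  if (min_height <= 0) stop("min_height must be > 0")
  if (min_enrichment < 1) stop("min_enrichment must be >= 1")
  strand <- enriched$strand
  cand <- enriched$pos[enriched$count >= min_height]
  if (!length(cand)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      height = numeric(0), enrichment = numeric(0)))
  }
  h <- profile_at(enriched, cand)
  u <- profile_at(unenriched, cand)
  ratio <- (h + pseudocount) / (u + pseudocount)
  keep <- ratio >= min_enrichment
  cand <- cand[keep]; h <- h[keep]; ratio <- ratio[keep]
  if (!length(cand)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      height = numeric(0), enrichment = numeric(0)))
  }
  is_max <- vapply(seq_along(cand), function(i) {
    p <- cand[i]
    nb <- setdiff(p + (-local_window):local_window, p)
    nc <- profile_at(enriched, nb)
    if (any(nc > h[i])) return(FALSE)
    ties <- nb[nc == h[i]]
    !any(vapply(ties, .more_5p, logical(1), q = p, strand = strand))
  }, logical(1))
  data.frame(pos = cand[is_max], strand = strand,
             height = h[is_max], enrichment = ratio[is_max])
}

#' Merge per-condition site lists within a window
#'
#' Single-linkage clustering per strand: sites (from any condition) whose
#' positions are within `window` nt of the next site join one cluster. Each
#' cluster is reported once, at the position with the highest summed height
#' across conditions (ties broken towards the 5'- or 3'-most position), with
#' the union of the contributing condition labels; a site seen in every
#' condition is flagged constitutive.
#'
#' @param per_condition named list (condition -> data.frame with `pos`,
#'   `strand`, `height`).
#' @param window merge half-width in nt.
#' @param tie `"five_prime"` (TSS convention) or `"three_prime"` (TEP
#'   convention) for equal summed heights.
#' @return data.frame with `pos`, `strand`, `height` (summed height at the
#'   representative position), `conditions` (comma-separated),
#'   `constitutive`.
#' @export
merge_sites <- function(per_condition, window = 5L,
                        tie = c("five_prime", "three_prime")) {
  tie <- match.arg(tie)
  conds <- names(per_condition)
  stopifnot(!is.null(conds))
  df <- do.call(rbind, lapply(conds, function(cc) {
    x <- per_condition[[cc]]
    if (!nrow(x)) return(NULL)
    data.frame(pos = x$pos, strand = x$strand, height = x$height,
               condition = cc, stringsAsFactors = FALSE)
  }))
  if (is.null(df) || !nrow(df)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      height = numeric(0), conditions = character(0),
                      constitutive = logical(0)))
  }
  out <- list()
  for (strand in unique(df$strand)) {
    s <- df[df$strand == strand, ]
    # summed height per distinct position
    agg <- rowsum(s$height, s$pos)
    pos <- as.integer(rownames(agg)); hsum <- as.numeric(agg)
    o <- order(pos); pos <- pos[o]; hsum <- hsum[o]
    cl <- cumsum(c(1L, as.integer(diff(pos) > window)))
    for (k in unique(cl)) {
      idx <- which(cl == k)
      hmax <- max(hsum[idx])
      best <- idx[hsum[idx] == hmax]
      rep_pos <- if ((tie == "five_prime") == (strand == "+")) {
        pos[min(best)]
      } else {
        pos[max(best)]
      }
      cc <- sort(unique(s$condition[s$pos %in% pos[idx]]))
      out[[length(out) + 1L]] <- data.frame(
        pos = rep_pos, strand = strand, height = hmax,
        conditions = paste(intersect(conds, cc), collapse = ","),
        constitutive = length(cc) == length(conds),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$pos), , drop = FALSE]
}

# genes annotated with their 5' start and 3' end on their own strand
.gene_frame <- function(annotation) {
  g <- annotation$genes
  g$start5 <- ifelse(g$strand == "+", g$start, g$end - 1L)  # first transcribed base
  g$end3 <- ifelse(g$strand == "+", g$end, g$start)         # half-open 3' boundary
  g
}

#' Classify merged TSSs against the gene annotation
#'
#' For each gene, same-strand sites within `upstream_window` nt upstream of
#' its start compete: the highest site becomes the primary (P) TSS, the
#' others secondary (S). Sites inside a same-strand gene body are internal
#' (I); sites within a gene body or its +/- `antisense_flank` nt on the
#' opposite strand are antisense (A); everything else is intergenic (N).
#' Precedence is P/S > I > A > N. A site upstream of several same-strand
#' genes is assigned to the nearest start (ties to the lower gene_id).
#'
#' @param sites merged site data.frame (from [merge_sites()] or a caller).
#' @param annotation a `genome_annotation`.
#' @param upstream_window nt upstream of a gene start searched for its TSS.
#' @param antisense_flank nt around a gene body counted as antisense.
#' @return the sites with columns `category` (P/S/I/A/N) and `gene` added.
#' @export
classify_tss <- function(sites, annotation, upstream_window = 300L,
                         antisense_flank = 100L) {
  g <- .gene_frame(annotation)
  n <- nrow(sites)
  category <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)

  assigned_gene <- rep(NA_character_, n)
  dist_to_start <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- sites$pos[i]; st <- sites$strand[i]
    cand <- g[g$strand == st, , drop = FALSE]
    d <- ifelse(cand$strand == "+", cand$start5 - p, p - cand$start5)
    hit <- which(d >= 1L & d <= upstream_window)
    if (length(hit)) {
      dd <- d[hit]
      best <- hit[dd == min(dd)]
      best <- best[order(cand$gene_id[best])][1L]
      assigned_gene[i] <- cand$gene_id[best]
      dist_to_start[i] <- d[best]
    }
  }
  for (gid in unique(stats::na.omit(assigned_gene))) {
    idx <- which(assigned_gene == gid)
    hmax <- max(sites$height[idx])
    strand <- sites$strand[idx][1L]
    winners <- idx[sites$height[idx] == hmax]
    prim <- if (strand == "+") winners[which.min(sites$pos[winners])]
            else winners[which.max(sites$pos[winners])]
    category[prim] <- "P"
    category[setdiff(idx, prim)] <- "S"
    gene[idx] <- gid
  }
  for (i in which(is.na(category))) {
    p <- sites$pos[i]; st <- sites$strand[i]
    sense <- g[g$strand == st & g$start <= p & p < g$end, , drop = FALSE]
    if (nrow(sense)) {
      category[i] <- "I"; gene[i] <- sense$gene_id[1L]; next
    }
    anti <- g[g$strand != st & (g$start - antisense_flank) <= p &
                p < (g$end + antisense_flank), , drop = FALSE]
    category[i] <- if (nrow(anti)) "A" else "N"
    if (nrow(anti)) gene[i] <- anti$gene_id[1L]
  }
  sites$category <- category
  sites$gene <- gene
  sites
}

#' 5'-UTR lengths and leaderless flags for classified TSSs
#'
#' The 5'-UTR length of a P or S TSS is the distance from the transcribed
#' +1 base to the start of its assigned gene on the sense strand; a
#' transcript is leaderless when that length is strictly below
#' `leaderless_max` (too short to hold a ribosome-binding site).
#'
#' @param records classified TSS data.frame (needs `category`, `gene`).
#' @param annotation a `genome_annotation`.
#' @param leaderless_max strict upper bound, nt.
#' @return list(`records` with `utr5`/`leaderless` columns, `summary` with
#'   median, leaderless count, leadered fraction, and a 10-nt histogram).
#' @export
utr5_and_leaderless <- function(records, annotation, leaderless_max = 10L) {
  g <- .gene_frame(annotation)
  utr5 <- rep(NA_integer_, nrow(records))
  ps <- which(records$category %in% c("P", "S"))
  for (i in ps) {
    gi <- g[g$gene_id == records$gene[i], ]
    u <- if (gi$strand == "+") gi$start5 - records$pos[i]
         else records$pos[i] - gi$start5
    if (u < 0L) stop("negative 5'-UTR length: TSS downstream of gene start ",
                     "(classification bug at pos ", records$pos[i], ")")
    utr5[i] <- u
  }
  records$utr5 <- utr5
  records$leaderless <- ifelse(is.na(utr5), NA, utr5 < leaderless_max)
  u <- utr5[!is.na(utr5)]
  summary <- list(
    median = if (length(u)) stats::median(u) else NA_real_,
    n_leaderless = sum(records$leaderless, na.rm = TRUE),
    leadered_fraction = if (length(u)) mean(u >= leaderless_max) else NA_real_,
    histogram = if (length(u)) table(cut(u, breaks = seq(0, max(u) + 10, 10),
                                         right = FALSE)) else NULL)
  list(records = records, summary = summary)
}

#' Positional base composition around sites
#'
#' Frequencies of A/C/G/T at each offset in [-flank, +flank] relative to the
#' site positions (offset 0 is the site itself, the biological +1 base).
#' Minus-strand windows are reverse-complemented so that all rows read in
#' the direction of transcription. Sites closer than `flank` to a contig
#' edge are excluded (with a message).
#'
#' @param sites data.frame with `pos`, `strand`.
#' @param seqs [Biostrings::DNAStringSet] of contig sequences (single
#'   contig) or a `genome_annotation`.
#' @param flank half-width in nt.
#' @return (2*flank+1) x 4 matrix of frequencies; each row sums to 1.
#' @export
base_composition <- function(sites, seqs, flank = 2L) {
  if (inherits(seqs, "genome_annotation")) seqs <- seqs$seqs
  if (!nrow(sites)) stop("empty site list")
  len <- Biostrings::width(seqs)[1L]
  ok <- sites$pos - flank >= 0L & sites$pos + flank < len
  if (any(!ok)) message(sum(!ok), " site(s) within ", flank,
                        " nt of a contig edge excluded")
  sites <- sites[ok, , drop = FALSE]
  if (!nrow(sites)) stop("no sites left after edge filtering")
  counts <- matrix(0, 2L * flank + 1L, 4L,
                   dimnames = list(as.character(-flank:flank),
                                   c("A", "C", "G", "T")))
  seqchar <- as.character(seqs[[1L]])
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    win <- substr(seqchar, p - flank + 1L, p + flank + 1L)
    ch <- strsplit(win, "", fixed = TRUE)[[1L]]
    if (sites$strand[i] == "-") ch <- .rc_chr(ch)
    m <- match(ch, c("A", "C", "G", "T"))
    keep <- !is.na(m)
    counts[cbind(which(keep), m[keep])] <-
      counts[cbind(which(keep), m[keep])] + 1
  }
  freq <- counts / rowSums(counts)
  freq
}
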