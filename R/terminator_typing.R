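# Intrinsic-terminator typing: fold the 40-nt window upstream of each TEP,
# split TEPs into highly structured (HS) and less structured (LS) at a
# free-energy threshold (the data median by default), type HS TEPs by the
# uridine content of the tract following the stem-loop (L-shaped U-rich vs
# I-shaped U-lacking), and quantify terminator readthrough from RNA-seq
# coverage.

# transcript-strand window of `width` nt ending at (and including) pos
.upstream_window <- function(seqs, pos, strand, width = 40L) {
  if (inherits(seqs, "genome_annotation")) seqs <- seqs$seqs
  len <- Biostrings::width(seqs)[1L]
  if (strand == "+") {
    from <- max(0L, pos - width + 1L); to <- pos
    s <- Biostrings::subseq(seqs[[1L]], from + 1L, to + 1L)
    list(seq = as.character(s), truncated = (pos - width + 1L) < 0L,
         g_of_idx = function(idx) from + idx - 1L)
  } else {
    from <- pos; to <- min(len - 1L, pos + width - 1L)
    s <- Biostrings::reverseComplement(
      Biostrings::subseq(seqs[[1L]], from + 1L, to + 1L))
    list(seq = as.character(s), truncated = (pos + width - 1L) > (len - 1L),
         g_of_idx = function(idx) to - idx + 1L)
  }
}

#' Fold the upstream windows of TEP records
#'
#' Extracts the `width`-nt transcript-strand sequence ending at each TEP and
#' folds it with [fold_window()]. Windows truncated at contig edges are
#' folded at their available length and flagged.
#'
#' @param records TEP data.frame (`pos`, `strand`).
#' @param seqs contig sequences or a `genome_annotation`.
#' @param width window width, nt.
#' @param temperature folding temperature, degrees Celsius.
#' @return records with `delta_g`, `structure`, `stem_length`,
#'   `loop_length`, `stem_close_genomic` (genomic 0-based position of the
#'   3'-most paired base of the 3'-most hairpin's closing helix, NA when
#'   unfolded) and `truncated` columns added.
#' @export
fold_teps <- function(records, seqs, width = 40L, temperature = 30) {
  n <- nrow(records)
  dg <- numeric(n); db <- character(n)
  stem <- rep(NA_integer_, n); loop <- rep(NA_integer_, n)
  close_g <- rep(NA_integer_, n); trunc <- logical(n)
  for (i in seq_len(n)) {
    w <- .upstream_window(seqs, records$pos[i], records$strand[i], width)
    f <- fold_window(w$seq, temperature)
    dg[i] <- f$delta_g; db[i] <- f$structure; trunc[i] <- w$truncated
    if (!is.null(f$hairpin3)) {
      stem[i] <- f$hairpin3$stem_length
      loop[i] <- f$hairpin3$loop_length
      close_g[i] <- w$g_of_idx(f$hairpin3$stem_close_pos)
    }
  }
  records$delta_g <- dg
  records$structure <- db
  records$stem_length <- stem
  records$loop_length <- loop
  records$stem_close_genomic <- close_g
  records$truncated <- trunc
  records
}

#' Split folded TEPs into highly and less structured classes
#'
#' HS: delta G <= threshold (inclusive); LS otherwise. With
#' `threshold = "median"` the threshold is the median of the delta G
#' distribution itself, so for odd n the HS class holds ceiling(n/2) sites.
#'
#' @param records folded TEP data.frame (needs `delta_g`).
#' @param threshold numeric threshold in kcal/mol, or `"median"`.
#' @return list(`records` with a `structure_class` column (HS/LS),
#'   `threshold_used`).
#' @export
split_hs_ls <- function(records, threshold = "median") {
  if (!nrow(records)) stop("empty TEP set")
  thr <- if (identical(threshold, "median")) {
    stats::median(records$delta_g)
  } else {
    stopifnot(is.numeric(threshold))
    threshold
  }
  records$structure_class <- ifelse(records$delta_g <= thr, "HS", "LS")
  list(records = records, threshold_used = thr)
}

#' Type HS TEPs by the U content following the stem-loop
#'
#' Counts uridines in the `window` nt immediately 3' of the stem-closing
#' base on the transcript strand. HS records with at least `min_u` uridines
#' are labelled `HS_U_RICH` (L-shaped terminator), the others `HS_U_LACK`
#' (I-shaped); LS records pass through with shape `LS`.
#'
#' @param records TEP data.frame after [split_hs_ls()] (needs
#'   `structure_class`, `stem_close_genomic`).
#' @param seqs contig sequences or a `genome_annotation`.
#' @param window nt scanned 3' of the stem.
#' @param min_u uridine threshold (inclusive).
#' @return records with `u_count` and `shape` columns added.
#' @export
type_u_content <- function(records, seqs, window = 10L, min_u = 3L) {
  if (inherits(seqs, "genome_annotation")) seqs <- seqs$seqs
  len <- Biostrings::width(seqs)[1L]
  seqchar <- as.character(seqs[[1L]])
  n <- nrow(records)
  u_count <- rep(NA_integer_, n)
  shape <- rep("LS", n)
  for (i in seq_len(n)) {
    if (records$structure_class[i] != "HS") next
    cg <- records$stem_close_genomic[i]
    if (is.na(cg)) {
      stop("HS TEP at pos ", records$pos[i],
           " has no hairpin (inconsistent fold annotation)")
    }
    if (records$strand[i] == "+") {
      a <- cg + 1L; b <- min(len - 1L, cg + window)
      tract <- substr(seqchar, a + 1L, b + 1L)
      u_count[i] <- lengths(regmatches(tract, gregexpr("T", tract)))
    } else {
      a <- max(0L, cg - window); b <- cg - 1L
      tract <- substr(seqchar, a + 1L, b + 1L)
      u_count[i] <- lengths(regmatches(tract, gregexpr("A", tract)))
    }
    shape[i] <- if (u_count[i] >= min_u) "HS_U_RICH" else "HS_U_LACK"
  }
  records$u_count <- u_count
  records$shape <- shape
  records
}

#' Positional nucleotide frequencies around TEPs, per shape class
#'
#' @param records shaped TEP data.frame (needs `shape`).
#' @param seqs contig sequences or a `genome_annotation`.
#' @param flank half-width, nt (default 50, giving 101 offsets).
#' @return named list of (2*flank+1) x 4 frequency matrices, one per shape
#'   class present; empty classes are skipped with a warning.
#' @export
positional_enrichment <- function(records, seqs, flank = 50L) {
  out <- list()
  for (cls in unique(records$shape)) {
    sub <- records[records$shape == cls, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no TEPs in class ", cls, "; skipped")
      next
    }
    out[[cls]] <- base_composition(sub, seqs, flank = flank)
  }
  out
}

#' Terminator readthrough fractions from RNA-seq coverage
#'
#' The readthrough fraction of a TEP is the mean coverage over the
#' `down_window` nt downstream of the TEP divided by the mean over the
#' `up_window` nt upstream (both transcript-strand oriented, the TEP
#' belonging to the upstream side), i.e. the fraction of transcription
#' leaking past the terminator. Per-class summaries are computed after
#' removing fractions above the `outlier_pctile` percentile of the pooled
#' distribution; TEPs with zero upstream coverage are undefined and
#' excluded (counted in the summary).
#'
#' @param records shaped TEP data.frame.
#' @param coverage list with `plus`/`minus` [end_profile()]s of RNA-seq
#'   coverage (normalized or raw; the ratio is scale-free).
#' @param up_window,down_window window widths, nt.
#' @param outlier_pctile percentile (0-100) above which pooled fractions
#'   are dropped from the class summaries.
#' @return list(`records` with a `readthrough` column, `summary`
#'   data.frame of per-class n/median, `n_undefined`,
#'   `outlier_cutoff`).
#' @export
readthrough_fraction <- function(records, coverage, up_window = 200L,
                                 down_window = 200L, outlier_pctile = 95) {
  n <- nrow(records)
  frac <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- records$pos[i]
    prof <- if (records$strand[i] == "+") coverage$plus else coverage$minus
    if (records$strand[i] == "+") {
      up <- profile_dense(prof, max(0L, p - up_window + 1L), p)
      dn <- profile_dense(prof, p + 1L, p + down_window)
    } else {
      up <- profile_dense(prof, p, p + up_window - 1L)
      dn <- profile_dense(prof, max(0L, p - down_window), max(0L, p - 1L))
    }
    mu <- mean(up)
    if (mu > 0) frac[i] <- mean(dn) / mu
  }
  records$readthrough <- frac
  pooled <- frac[!is.na(frac)]
  cutoff <- if (length(pooled)) stats::quantile(pooled, outlier_pctile / 100)
            else NA_real_
  keep <- !is.na(frac) & frac <= cutoff
  cls <- if ("shape" %in% names(records)) records$shape else
    rep("all", n)
  summ <- do.call(rbind, lapply(unique(cls), function(cc) {
    sel <- keep & cls == cc
    data.frame(class = cc, n = sum(sel),
               median_readthrough = if (any(sel)) stats::median(frac[sel])
                                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = records, summary = summ,
       n_undefined = sum(is.na(frac)), outlier_cutoff = unname(cutoff))
}

#' Stem and loop length distributions with pairwise class comparisons
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparisons of the 3'-most
#' hairpin stem and loop lengths between shape classes. Records without a
#' hairpin are excluded; classes with fewer than 3 structured members are
#' skipped.
#'
#' @param records shaped TEP data.frame with `stem_length`, `loop_length`.
#' @return list(`distributions` per class, `comparisons` data.frame with U
#'   statistic and p-value per class pair and metric).
#' @export
stem_loop_metrics <- function(records) {
  ok <- !is.na(records$stem_length)
  rec <- records[ok, , drop = FALSE]
  classes <- unique(rec$shape)
  dist <- lapply(stats::setNames(classes, classes), function(cc) {
    list(stem = rec$stem_length[rec$shape == cc],
         loop = rec$loop_length[rec$shape == cc])
  })
  comp <- list()
  if (length(classes) >= 2L) {
    prs <- utils::combn(classes, 2L)
    for (k in seq_len(ncol(prs))) {
      c1 <- prs[1L, k]; c2 <- prs[2L, k]
      for (metric in c("stem", "loop")) {
        x <- dist[[c1]][[metric]]; y <- dist[[c2]][[metric]]
        if (length(x) < 3L || length(y) < 3L) next
        wt <- stats::wilcox.test(x, y, exact = FALSE)
        comp[[length(comp) + 1L]] <- data.frame(
          class1 = c1, class2 = c2, metric = metric,
          U = unname(wt$statistic), p_value = wt$p.value,
          median1 = stats::median(x), median2 = stats::median(y),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(distributions = dist,
       comparisons = if (length(comp)) do.call(rbind, comp) else NULL)
}
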