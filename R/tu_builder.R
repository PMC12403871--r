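# Transcription-unit assembly and functional-relatedness statistics.
#
# A transcription unit (TU) is the region between a TSS and the nearest
# downstream TEP on the same strand, provided the TEP lies within a maximum
# span and before the gene block of the next primary TSS. TUs are
# categorized by the genes they fully contain: monocistronic (1),
# polycistronic (>= 2), or gene-less (cis-regulatory when ending at a
# cis-regulatory TEP, intergenic otherwise).

#' Assemble transcription units from classified TSS and TEP lists
#'
#' Per condition and strand, each active TSS is paired with the nearest
#' downstream active TEP that (i) lies within `max_span` nt and (ii) does
#' not cross into the gene block of the next primary TSS. Per-condition TUs
#' whose endpoints agree within +/- `merge_window` nt are merged, with the
#' union of condition labels.
#'
#' @param tss_records classified TSS data.frame (`pos`, `strand`,
#'   `conditions`, `category`, `gene`, `height`).
#' @param tep_records classified TEP data.frame (`pos`, `strand`,
#'   `conditions`, `category`).
#' @param annotation a `genome_annotation`.
#' @param max_span maximum TSS-TEP span, nt.
#' @param merge_window endpoint tolerance when merging conditions, nt.
#' @param conditions condition labels to assemble over (default: all labels
#'   appearing in the TSS records).
#' @return data.frame of TUs: `tss_pos`, `tep_pos`, `strand`, `span_start`,
#'   `span_end` (0-based half-open, forward frame), `genes`
#'   (comma-separated, 5' to 3'), `n_genes`, `category`, `conditions`.
#' @export
assemble_tus <- function(tss_records, tep_records, annotation,
                         max_span = 15000L, merge_window = 5L,
                         conditions = NULL) {
  g <- .gene_frame(annotation)
  if (is.null(conditions)) {
    conditions <- unique(unlist(strsplit(tss_records$conditions, ",")))
  }
  per_cond <- list()
  for (cond in conditions) {
    tss <- tss_records[.cond_has(tss_records$conditions, cond), , drop = FALSE]
    tep <- tep_records[.cond_has(tep_records$conditions, cond), , drop = FALSE]
    tus <- list()
    for (strand in c("+", "-")) {
      up <- strand == "+"
      st <- tss[tss$strand == strand, , drop = FALSE]
      te <- tep[tep$strand == strand, , drop = FALSE]
      if (!nrow(st) || !nrow(te)) next
      st <- st[order(st$pos, decreasing = !up), , drop = FALSE]  # 5' -> 3'
      for (i in seq_len(nrow(st))) {
        p <- st$pos[i]
        # limit: 5' start of the next primary TSS's assigned gene
        lim <- NA_integer_
        nxt <- st[-seq_len(i), , drop = FALSE]
        nxt <- nxt[nxt$category == "P" & !is.na(nxt$gene), , drop = FALSE]
        if (nrow(nxt)) {
          gstart <- g$start5[match(nxt$gene[1L], g$gene_id)]
          lim <- gstart
        }
        d <- if (up) te$pos - p else p - te$pos
        ok <- d > 0L & d <= max_span
        if (!is.na(lim)) {
          ok <- ok & (if (up) te$pos < lim else te$pos > lim)
        }
        if (!any(ok)) next
        cand <- which(ok)
        j <- cand[which.min(d[cand])]
        q <- te$pos[j]
        if ((up && q <= p) || (!up && q >= p)) {
          stop("TEP not downstream of its TSS (pairing bug)")
        }
        a <- min(p, q); b <- max(p, q) + 1L
        inside <- g$strand == strand & g$start >= a & g$end <= b
        gid <- g$gene_id[inside]
        ord <- order(g$start[inside], decreasing = !up)
        gid <- gid[ord]
        category <- if (length(gid) >= 2L) "polycistronic"
          else if (length(gid) == 1L) "monocistronic"
          else if (!is.na(te$category[j]) && te$category[j] == "C")
            "cis_regulatory"
          else "intergenic"
        tus[[length(tus) + 1L]] <- data.frame(
          tss_pos = p, tep_pos = q, strand = strand,
          span_start = a, span_end = b,
          genes = paste(gid, collapse = ","), n_genes = length(gid),
          category = category, conditions = cond,
          tss_height = st$height[i], stringsAsFactors = FALSE)
      }
    }
    per_cond[[cond]] <- if (length(tus)) do.call(rbind, tus) else NULL
  }
  all_tus <- do.call(rbind, per_cond)
  if (is.null(all_tus) || !nrow(all_tus)) {
    return(data.frame(tss_pos = integer(0), tep_pos = integer(0),
                      strand = character(0), span_start = integer(0),
                      span_end = integer(0), genes = character(0),
                      n_genes = integer(0), category = character(0),
                      conditions = character(0)))
  }
  # merge across conditions: both endpoints within merge_window
  merged <- list()
  used <- rep(FALSE, nrow(all_tus))
  ord <- order(-all_tus$tss_height)
  for (i in ord) {
    if (used[i]) next
    same <- which(!used & all_tus$strand == all_tus$strand[i] &
                    abs(all_tus$tss_pos - all_tus$tss_pos[i]) <= merge_window &
                    abs(all_tus$tep_pos - all_tus$tep_pos[i]) <= merge_window)
    used[same] <- TRUE
    rec <- all_tus[i, , drop = FALSE]
    cc <- unique(all_tus$conditions[same])
    rec$conditions <- paste(intersect(conditions, cc), collapse = ",")
    merged[[length(merged) + 1L]] <- rec
  }
  res <- do.call(rbind, merged)
  res$tss_height <- NULL
  res <- res[order(res$strand, res$span_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Category counts and genes-per-TU summary
#'
#' @param tus TU data.frame from [assemble_tus()].
#' @return list(`counts` named vector over the four categories (summing to
#'   the TU total), `median_genes_polycistronic`, `n_tus`).
#' @export
categorize_and_summarize <- function(tus) {
  cats <- c("monocistronic", "polycistronic", "cis_regulatory", "intergenic")
  counts <- vapply(cats, function(cc) sum(tus$category == cc), integer(1))
  stopifnot(sum(counts) == nrow(tus))
  poly <- tus$n_genes[tus$category == "polycistronic"]
  list(counts = counts,
       median_genes_polycistronic = if (length(poly)) stats::median(poly)
                                    else NA_real_,
       n_tus = nrow(tus))
}

#' Functional enrichment score of one gene set
#'
#' The maximum number of genes sharing a single COG category divided by the
#' number of distinct COG categories present; genes without a category are
#' excluded. The literal ratio can exceed 1 (all genes in one category);
#' `mode = "per_gene"` divides by the number of COG-annotated genes
#' instead, bounding the score at 1.
#'
#' @param cogs character vector of single-letter COG categories (NA =
#'   unassigned).
#' @param mode `"literal"` or `"per_gene"`.
#' @return list(`score` (NA when no gene has a category),
#'   `n_genes_with_cog`, `n_categories`).
#' @export
functional_enrichment_score <- function(cogs, mode = c("literal", "per_gene")) {
  mode <- match.arg(mode)
  cc <- cogs[!is.na(cogs) & cogs != ""]
  if (!length(cc)) {
    return(list(score = NA_real_, n_genes_with_cog = 0L, n_categories = 0L))
  }
  tab <- table(cc)
  denom <- if (mode == "literal") length(tab) else length(cc)
  list(score = max(tab) / denom,
       n_genes_with_cog = length(cc), n_categories = length(tab))
}

#' Enrichment scores for a TU table
#'
#' @param tus TU data.frame (`genes` comma-separated).
#' @param annotation a `genome_annotation` carrying gene COG categories.
#' @param mode see [functional_enrichment_score()].
#' @return numeric vector of scores (NA for TUs without COG-annotated
#'   genes).
#' @export
tu_enrichment_scores <- function(tus, annotation, mode = "literal") {
  g <- annotation$genes
  vapply(tus$genes, function(gl) {
    gid <- strsplit(gl, ",", fixed = TRUE)[[1L]]
    gid <- gid[nzchar(gid)]
    functional_enrichment_score(g$cog[match(gid, g$gene_id)], mode)$score
  }, numeric(1), USE.NAMES = FALSE)
}

#' Random-neighbor baseline for the functional enrichment score
#'
#' Draws sets of consecutive same-strand genes with sizes sampled from the
#' observed polycistronic TU sizes, scores each with the same formula, and
#' (when observed scores are supplied) compares the two distributions with
#' a two-sided Mann-Whitney test.
#'
#' @param annotation a `genome_annotation`.
#' @param tu_sizes integer vector of observed polycistronic TU gene counts.
#' @param n_draws number of random gene sets.
#' @param seed RNG seed.
#' @param observed_scores optional numeric vector of observed TU scores.
#' @param mode see [functional_enrichment_score()].
#' @param max_retry resampling cap when a drawn run exceeds the strand run.
#' @return list(`scores`, and with observed scores also `U`, `p_value`).
#' @export
random_neighbor_baseline <- function(annotation, tu_sizes, n_draws = 1000L,
                                     seed = 1L, observed_scores = NULL,
                                     mode = "literal", max_retry = 1000L) {
  stopifnot(length(tu_sizes) >= 1L)
  set.seed(seed)
  g <- annotation$genes
  scores <- numeric(0)
  for (d in seq_len(n_draws)) {
    k <- sample(rep(tu_sizes, 2L), 1L)
    got <- FALSE
    for (r in seq_len(max_retry)) {
      i <- sample.int(nrow(g), 1L)
      same <- which(g$contig_id == g$contig_id[i] & g$strand == g$strand[i])
      at <- match(i, same)
      if (at + k - 1L > length(same)) next
      run <- same[at:(at + k - 1L)]
      sc <- functional_enrichment_score(g$cog[run], mode)$score
      if (!is.na(sc)) { scores <- c(scores, sc); got <- TRUE; break }
    }
    if (!got) stop("could not draw a same-strand gene run of size ", k,
                   " after ", max_retry, " tries")
  }
  out <- list(scores = scores)
  if (!is.null(observed_scores)) {
    obs <- observed_scores[!is.na(observed_scores)]
    wt <- stats::wilcox.test(obs, scores, exact = FALSE)
    out$U <- unname(wt$statistic)
    out$p_value <- wt$p.value
  }
  out
}
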