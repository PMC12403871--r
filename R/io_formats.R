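# External formats and coordinate conventions.
#
# Internally every feature lives in 0-based half-open coordinates on the
# forward strand; minus-strand features carry a strand flag. Conversion to
# the 1-based conventions of GFF3 and site tables happens only at the I/O
# edges. bedGraph intervals are 0-based half-open already and expand to a
# sparse per-position count map.

#' Read a genome FASTA file
#'
#' @param path path to a FASTA file.
#' @return [Biostrings::DNAStringSet] (uppercased, U converted to T), one
#'   entry per record, named by the first token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("Uu", "Tt", as.character(raw))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal characters in FASTA record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Construct a genome annotation
#'
#' @param seqs [Biostrings::DNAStringSet] of contig sequences.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (+/-), `cog` (single-letter COG
#'   category or NA).
#' @return object of class `genome_annotation` (list with `seqs`, `genes`;
#'   genes sorted by contig then start).
#' @export
genome_annotation <- function(seqs, genes) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    stop("genes must have columns: ", paste(need, collapse = ", "))
  }
  if (!"cog" %in% names(genes)) genes$cog <- NA_character_
  if (!all(genes$contig_id %in% names(seqs))) {
    stop("gene contig(s) absent from sequences: ",
         paste(setdiff(genes$contig_id, names(seqs)), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  len <- Biostrings::width(seqs)[match(genes$contig_id, names(seqs))]
  if (any(genes$start < 0L | genes$start >= genes$end | genes$end > len)) {
    stop("gene interval out of bounds or malformed")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(seqs = seqs, genes = genes), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d contig(s) (%s nt), %d genes\n",
              length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Keeps `gene` features (or `CDS` when no `gene` features are present),
#' converts 1-based inclusive GFF coordinates to the internal 0-based
#' half-open frame, and parses an optional `cog=X` attribute into the COG
#' category column.
#'
#' @param path path to a GFF3 file.
#' @param seqs contig sequences the annotation must be consistent with.
#' @return a `genome_annotation`.
#' @export
read_gff3 <- function(path, seqs) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3: ",
                                          conditionMessage(e)))
  types <- as.character(gr$type)
  keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene/CDS features in GFF3: ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene features must have strand + or - (found '.'/'*')")
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$locus_tag
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene_", seq_along(gr))
  cog <- if ("cog" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$cog)
  } else NA_character_
  genes <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    cog = cog,
    stringsAsFactors = FALSE
  )
  genome_annotation(seqs, genes)
}

#' Construct a strand-specific end-count profile
#'
#' Sparse per-position counts of read 5'- or 3'-ends (or coverage) for one
#' library and one strand of one contig.
#'
#' @param contig contig id.
#' @param strand "+" or "-".
#' @param pos integer vector of 0-based positions.
#' @param count numeric vector of positive counts, parallel to `pos`.
#' @param meta list with `assay` (one of "dRNA", "Term", "RNAseq-coverage"),
#'   `condition`, `replicate`, and optional `enriched` flag.
#' @param contig_length optional length used for bounds checking.
#' @return object of class `end_profile`.
#' @export
end_profile <- function(contig, strand, pos, count,
                        meta = list(assay = "dRNA", condition = "c1",
                                    replicate = 1L, enriched = NA),
                        contig_length = NULL) {
  stopifnot(strand %in% c("+", "-"), length(pos) == length(count))
  if (any(count < 0)) stop("negative counts are not allowed")
  if (any(pos < 0)) stop("negative positions are not allowed")
  if (!is.null(contig_length) && length(pos) && max(pos) >= contig_length) {
    stop("position beyond contig end")
  }
  keep <- count > 0
  pos <- as.integer(pos[keep]); count <- as.numeric(count[keep])
  o <- order(pos)
  if (anyDuplicated(pos)) stop("duplicate positions in end-count profile")
  structure(list(contig = contig, strand = strand,
                 pos = pos[o], count = count[o], meta = meta),
            class = "end_profile")
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("end_profile %s(%s): %d nonzero positions, total %.0f [%s %s rep%s]\n",
              x$contig, x$strand, length(x$pos), sum(x$count),
              x$meta$assay %||% "?", x$meta$condition %||% "?",
              x$meta$replicate %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a strand pair of bedGraph end-count files
#'
#' bedGraph intervals (0-based half-open) are expanded to per-position
#' counts; zero-valued intervals are dropped. Overlapping intervals or
#' negative values on either strand are rejected.
#'
#' @param path_plus,path_minus bedGraph files for the + and - strands.
#' @param meta library metadata list (see [end_profile()]).
#' @param contig restrict to this contig; required when a file covers more
#'   than one contig.
#' @param contig_length optional bounds check.
#' @return list with elements `plus` and `minus`, each an `end_profile`.
#' @export
read_endcounts_bedgraph <- function(path_plus, path_minus, meta = list(),
                                    contig = NULL, contig_length = NULL) {
  read_one <- function(path, strand) {
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                   error = function(e) stop("malformed bedGraph '", path,
                                            "': ", conditionMessage(e)))
    cids <- as.character(GenomicRanges::seqnames(gr))
    if (!is.null(contig)) {
      gr <- gr[cids == contig]; cids <- cids[cids == contig]
    }
    if (length(gr) == 0L) {
      if (is.null(contig)) stop("empty bedGraph: ", path)
      return(end_profile(contig, strand, integer(0), numeric(0), meta))
    }
    if (length(unique(cids)) > 1L) {
      stop("bedGraph covers several contigs; pass `contig` to select one")
    }
    if (any(gr$score < 0)) stop("negative values in bedGraph: ", path)
    red <- GenomicRanges::reduce(gr)
    if (sum(BiocGenerics::width(red)) < sum(BiocGenerics::width(gr))) {
      stop("overlapping intervals in bedGraph: ", path)
    }
    w <- BiocGenerics::width(gr)
    pos <- sequence(w, from = BiocGenerics::start(gr) - 1L)  # 0-based
    count <- rep(gr$score, w)
    end_profile(unique(cids), strand, pos, count, meta,
                contig_length = contig_length)
  }
  list(plus = read_one(path_plus, "+"), minus = read_one(path_minus, "-"))
}

#' Write an end-count profile as bedGraph
#'
#' Runs of consecutive positions with equal counts are collapsed into
#' intervals; reading the file back reproduces the sparse map exactly.
#'
#' @param profile an `end_profile`.
#' @param path output path.
#' @export
write_endcounts_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "end_profile"))
  pos <- profile$pos; count <- profile$count
  if (length(pos) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  brk <- c(TRUE, diff(pos) != 1L | diff(count) != 0)
  run <- cumsum(brk)
  start0 <- tapply(pos, run, min)
  end0 <- tapply(pos, run, max) + 1L
  val <- tapply(count, run, `[`, 1L)
  df <- data.frame(chrom = profile$contig, start = as.integer(start0),
                   end = as.integer(end0), value = as.numeric(val))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a site or TU table as TSV
#'
#' Positions named in `pos_cols` are converted from the internal 0-based
#' frame to 1-based for output (the convention of published site tables).
#'
#' @param records data.frame of TSS/TEP/TU records.
#' @param path output path.
#' @param pos_cols character vector of 0-based position columns to shift.
#' @export
write_feature_table <- function(records, path,
                                pos_cols = intersect(c("pos", "tss_pos", "tep_pos"),
                                                     names(records))) {
  stopifnot(is.data.frame(records))
  out <- records
  for (cc in pos_cols) out[[cc]] <- out[[cc]] + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @param pos_cols 1-based position columns to convert back to 0-based.
#' @return data.frame in internal coordinates.
#' @export
read_feature_table <- function(path,
                               pos_cols = c("pos", "tss_pos", "tep_pos")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  for (cc in intersect(pos_cols, names(df))) df[[cc]] <- df[[cc]] - 1L
  df
}

#' Dense count vector over a position range
#'
#' @param profile an [end_profile()].
#' @param from,to 0-based inclusive range.
#' @return numeric vector of counts with zeros filled in.
#' @export
profile_dense <- function(profile, from, to) {
  v <- numeric(to - from + 1L)
  sel <- profile$pos >= from & profile$pos <= to
  v[profile$pos[sel] - from + 1L] <- profile$count[sel]
  v
}

#' Sum end-count profiles position-wise
#'
#' @param profiles list of [end_profile()]s on the same contig and strand
#'   (e.g. replicates to pool before site calling).
#' @return a single `end_profile` with summed counts.
#' @export
profile_sum <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  contig <- profiles[[1L]]$contig; strand <- profiles[[1L]]$strand
  for (p in profiles) {
    if (p$contig != contig || p$strand != strand) {
      stop("cannot sum profiles from different contigs/strands")
    }
  }
  pos <- unlist(lapply(profiles, `[[`, "pos"))
  count <- unlist(lapply(profiles, `[[`, "count"))
  agg <- rowsum(count, pos)
  end_profile(contig, strand, as.integer(rownames(agg)), as.numeric(agg),
              meta = profiles[[1L]]$meta)
}

#' Counts at given positions
#'
#' @param profile an [end_profile()].
#' @param at integer positions (0-based).
#' @return numeric counts, 0 where the profile has no entry.
#' @export
profile_at <- function(profile, at) {
  idx <- match(at, profile$pos)
  out <- numeric(length(at))
  out[!is.na(idx)] <- profile$count[idx[!is.na(idx)]]
  out
}
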