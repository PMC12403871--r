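# Synthetic high-GC genome and library simulator.
#
# The generator plants operons (runs of same-strand genes) along an i.i.d.
# background genome, gives each operon one transcription start site (TSS)
# 20-300 nt upstream of its first gene and one transcript 3'-end position
# (TEP) downstream of its last gene, and emulates the three library types of
# a dRNA-seq / Term-seq / RNA-seq experiment as Poisson end-count tracks.
# Terminators come in three planted flavours: L-shaped (GC stem-loop with a
# >= 4 nt U-tract), I-shaped (same stem-loop, U-poor tail), or unstructured
# (no planted hairpin). Everything is deterministic under the config seed.

.COG_LETTERS <- c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                  "M", "N", "O", "P", "Q", "T", "U", "V")

#' Simulation configuration
#'
#' Defaults describe the benchmark regime used throughout the package's
#' validation: a 100 kb contig at 65% GC carrying 60 genes, two conditions
#' with two replicates each, TSS peaks of mean height 300 over a background
#' of 0.1 counts/nt, 8-fold 5'-end enrichment in the TEX-treated library,
#' and planted terminator readthrough of 5% (L-shaped), 10% (I-shaped) and
#' 50% (unstructured).
#'
#' @param genome_length contig length, nt (>= 10 kb).
#' @param gc_fraction background GC content (0-1).
#' @param n_genes number of genes to place.
#' @param operon_sizes vector of operon sizes to sample from (default 1:
#'   every gene is its own transcription unit).
#' @param conditions condition labels.
#' @param constitutive_fraction fraction of TSSs active in all conditions.
#' @param tep_shared_fraction fraction of TEPs active in all conditions.
#' @param shape_mix named fractions of TEP shapes `L`, `I`, `U`
#'   (must sum to 1).
#' @param stem_range GC stem lengths (bp) sampled for planted hairpins.
#' @param loop_range hairpin loop lengths (nt).
#' @param tex_enrichment fold 5'-end enrichment of the treated dRNA library.
#' @param background_rate mean background counts per nt.
#' @param peak_height mean counts at a planted site.
#' @param readthrough named fractions of coverage leaking past `L`, `I`,
#'   `U` terminators.
#' @param n_replicates replicates per condition.
#' @param purine_bias probability that the transcribed +1 base is A or G.
#' @param expression_mean mean RNA-seq coverage of a transcription unit.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5L,
                       gc_fraction = 0.65,
                       n_genes = 60L,
                       operon_sizes = 1L,
                       conditions = c("NMS", "ANMS"),
                       constitutive_fraction = 0.75,
                       tep_shared_fraction = 0.55,
                       shape_mix = c(L = 0.15, I = 0.35, U = 0.5),
                       stem_range = 8:12,
                       loop_range = 4:8,
                       tex_enrichment = 8,
                       background_rate = 0.1,
                       peak_height = 300,
                       readthrough = c(L = 0.05, I = 0.1, U = 0.5),
                       n_replicates = 2L,
                       purine_bias = 0.86,
                       expression_mean = 30,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              operon_sizes = as.integer(operon_sizes),
              conditions = conditions,
              constitutive_fraction = constitutive_fraction,
              tep_shared_fraction = tep_shared_fraction,
              shape_mix = shape_mix, stem_range = as.integer(stem_range),
              loop_range = as.integer(loop_range),
              tex_enrichment = tex_enrichment,
              background_rate = background_rate, peak_height = peak_height,
              readthrough = readthrough,
              n_replicates = as.integer(n_replicates),
              purine_bias = purine_bias, expression_mean = expression_mean,
              seed = as.integer(seed))
  if (cfg$genome_length < 1e4L) stop("genome_length must be >= 10 kb")
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1) stop("gc_fraction in [0,1]")
  if (abs(sum(cfg$shape_mix) - 1) > 1e-8) stop("shape_mix must sum to 1")
  if (!all(names(cfg$shape_mix) == c("L", "I", "U"))) {
    stop("shape_mix must be named L, I, U")
  }
  if (!all(names(cfg$readthrough) == c("L", "I", "U"))) {
    stop("readthrough must be named L, I, U")
  }
  frac <- c(cfg$constitutive_fraction, cfg$tep_shared_fraction,
            cfg$purine_bias, cfg$readthrough)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0,1]")
  if (cfg$background_rate < 0 || cfg$peak_height < 0 ||
      cfg$tex_enrichment < 1) {
    stop("rates must be >= 0 and tex_enrichment >= 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rc_chr <- function(x) rev(chartr("ACGT", "TGCA", x))

.sample_bg <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a genome with planted transcription units
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a `genome_annotation`) and `truth`
#'   (list of data.frames `tss`, `tep`, `operons` giving the planted sites,
#'   their condition sets, terminator shapes and gene assignments).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  genome <- .sample_bg(L, config$gc_fraction)

  conds <- config$conditions
  all_cond <- paste(conds, collapse = ",")
  shapes <- names(config$shape_mix)

  # stratified shape assignment: plant class counts proportional to the
  # configured mix (shuffled), so the realized class fractions match the
  # mix up to rounding rather than drifting binomially
  n_shape <- diff(round(cumsum(c(0, config$shape_mix)) * config$n_genes))
  shape_queue <- sample(rep(shapes, times = n_shape))

  genes <- list(); tss <- list(); tep <- list(); ops <- list()
  cursor <- 400L
  placed <- 0L; op_id <- 0L
  while (placed < config$n_genes) {
    k <- min(sample(rep(config$operon_sizes, 2L), 1L),
             config$n_genes - placed)
    strand <- sample(c("+", "-"), 1L)
    shape <- shape_queue[op_id + 1L]
    d5 <- sample(20:300, 1L)
    glen <- sample(500:1000, k, replace = TRUE)
    ggap <- if (k > 1L) sample(20:100, k - 1L, replace = TRUE) else integer(0)

    # local layout in transcription direction, 0-based; TSS at 0
    gstart <- integer(k); gend <- integer(k)
    at <- d5
    for (g in seq_len(k)) {
      gstart[g] <- at; gend[g] <- at + glen[g]
      at <- gend[g] + if (g < k) ggap[g] else 0L
    }
    E <- gend[k]

    planted <- NULL; plant_at <- NA_integer_
    stem_close_local <- NA_integer_
    if (shape %in% c("L", "I")) {
      s <- sample(20:80, 1L)
      st <- sample(rep(config$stem_range, 2L), 1L)
      lp <- sample(rep(config$loop_range, 2L), 1L)
      left <- sample(c("G", "C"), st, replace = TRUE)
      hair <- c(left, .sample_bg(lp, config$gc_fraction), .rc_chr(left))
      plant_at <- E + s
      stem_close_local <- plant_at + 2L * st + lp - 1L
      if (shape == "L") {
        tail_len <- sample(4:8, 1L)
        planted <- c(hair, rep("T", tail_len))
        tep_local <- stem_close_local + tail_len
      } else {
        repeat {
          post <- .sample_bg(10L, config$gc_fraction)
          if (sum(post == "T") <= 2L) break
        }
        planted <- c(hair, post)
        tep_local <- stem_close_local + sample(2:6, 1L)
      }
    } else {
      tep_local <- E + sample(30:150, 1L) - 1L
    }
    blen <- tep_local + 1L

    if (cursor + blen > L - 400L) break
    bs <- cursor
    loc2gen <- function(p) if (strand == "+") bs + p else bs + (blen - 1L - p)

    # plant terminator sequence
    if (!is.null(planted)) {
      if (strand == "+") {
        genome[(bs + plant_at + 1L):(bs + plant_at + length(planted))] <- planted
      } else {
        gpos <- loc2gen(plant_at + length(planted) - 1L):loc2gen(plant_at)
        genome[gpos + 1L] <- .rc_chr(planted)
      }
    }
    # +1 base of the transcript
    b1 <- if (stats::runif(1) < config$purine_bias) sample(c("A", "G"), 1L)
          else sample(c("C", "T"), 1L)
    gp <- loc2gen(0L)
    genome[gp + 1L] <- if (strand == "+") b1 else chartr("ACGT", "TGCA", b1)

    op_id <- op_id + 1L
    cog <- if (k >= 2L) rep(sample(.COG_LETTERS, 1L), k)
           else sample(.COG_LETTERS, k, replace = TRUE)
    gid <- sprintf("g%04d", placed + seq_len(k))
    for (g in seq_len(k)) {
      a <- loc2gen(gstart[g]); b2 <- loc2gen(gend[g] - 1L)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid[g], contig_id = "synth_1",
        start = min(a, b2), end = max(a, b2) + 1L,
        strand = strand, cog = cog[g], stringsAsFactors = FALSE)
    }
    tss_cond <- if (stats::runif(1) < config$constitutive_fraction) all_cond
                else sample(conds, 1L)
    tep_cond <- if (stats::runif(1) < config$tep_shared_fraction) all_cond
                else sample(conds, 1L)
    level <- stats::rlnorm(1, log(config$expression_mean), 0.5)
    tss[[op_id]] <- data.frame(
      pos = loc2gen(0L), strand = strand, conditions = tss_cond,
      operon_id = op_id, gene_id = gid[1L], stringsAsFactors = FALSE)
    tep[[op_id]] <- data.frame(
      pos = loc2gen(tep_local), strand = strand, conditions = tep_cond,
      shape = shape, operon_id = op_id, gene_id = gid[k],
      stem_close = if (is.na(stem_close_local)) NA_integer_
                   else loc2gen(stem_close_local),
      stringsAsFactors = FALSE)
    ops[[op_id]] <- data.frame(
      operon_id = op_id, strand = strand, n_genes = k,
      gene_ids = paste(gid, collapse = ","),
      tss_pos = loc2gen(0L), tep_pos = loc2gen(tep_local),
      shape = shape, level = level, stringsAsFactors = FALSE)

    placed <- placed + k
    cursor <- bs + blen + sample(400:600, 1L)
  }
  if (placed < config$n_genes) {
    stop("genome too short to place ", config$n_genes,
         " genes without overlap (placed ", placed, ")")
  }

  seqs <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(seqs) <- "synth_1"
  ann <- genome_annotation(seqs, do.call(rbind, genes))
  truth <- list(tss = do.call(rbind, tss), tep = do.call(rbind, tep),
                operons = do.call(rbind, ops))
  list(annotation = ann, truth = truth)
}

.cond_has <- function(conditions, cond) {
  vapply(strsplit(conditions, ",", fixed = TRUE),
         function(x) cond %in% x, logical(1))
}

.sparse_pois <- function(lambda, contig, strand, meta) {
  x <- stats::rpois(length(lambda), lambda)
  nz <- which(x > 0L)
  end_profile(contig, strand, nz - 1L, x[nz], meta)
}

#' Simulate dRNA-seq, Term-seq and RNA-seq tracks
#'
#' For each condition and replicate: the TEX-treated (enriched) dRNA track
#' is Poisson background plus Poisson peaks of mean `peak_height` at the
#' planted TSSs active in that condition; the untreated track carries the
#' same peaks attenuated `tex_enrichment`-fold; the Term-seq 3'-end track is
#' analogous at planted TEPs; RNA-seq coverage is piecewise constant along
#' each transcription unit with a shape-dependent fraction leaking 200 nt
#' past the terminator, plus Poisson noise.
#'
#' @param annotation,truth output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return nested list `libs$drna[[cond]][[rep]]$enriched/$unenriched`,
#'   `libs$term[[cond]][[rep]]`, `libs$cov[[cond]][[rep]]`, each holding
#'   `plus`/`minus` [end_profile()]s.
#' @export
simulate_libraries <- function(annotation, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- config$genome_length
  contig <- names(annotation$seqs)[1L]
  bg <- config$background_rate
  pk <- config$peak_height
  conds <- config$conditions

  cov_lambda <- list(`+` = rep(bg, L), `-` = rep(bg, L))
  for (r in seq_len(nrow(truth$operons))) {
    op <- truth$operons[r, ]
    rt <- config$readthrough[[op$shape]]
    a <- min(op$tss_pos, op$tep_pos); b <- max(op$tss_pos, op$tep_pos)
    cov_lambda[[op$strand]][(a + 1L):(b + 1L)] <-
      cov_lambda[[op$strand]][(a + 1L):(b + 1L)] + op$level
    if (op$strand == "+") {
      dn <- (op$tep_pos + 1L):min(op$tep_pos + 200L, L - 1L)
    } else {
      dn <- max(op$tep_pos - 200L, 0L):(op$tep_pos - 1L)
    }
    cov_lambda[[op$strand]][dn + 1L] <-
      cov_lambda[[op$strand]][dn + 1L] + rt * op$level
  }

  drna <- list(); term <- list(); cov <- list()
  for (cond in conds) {
    drna[[cond]] <- list(); term[[cond]] <- list(); cov[[cond]] <- list()
    tss_act <- truth$tss[.cond_has(truth$tss$conditions, cond), ]
    tep_act <- truth$tep[.cond_has(truth$tep$conditions, cond), ]
    for (rep_i in seq_len(config$n_replicates)) {
      mk <- function(assay, enr) list(assay = assay, condition = cond,
                                      replicate = rep_i, enriched = enr)
      one_strand <- function(strand, sites, height, meta) {
        lam <- rep(bg, L)
        p <- sites$pos[sites$strand == strand]
        lam[p + 1L] <- lam[p + 1L] + height
        .sparse_pois(lam, contig, strand, meta)
      }
      drna[[cond]][[rep_i]] <- list(
        enriched = list(
          plus = one_strand("+", tss_act, pk, mk("dRNA", TRUE)),
          minus = one_strand("-", tss_act, pk, mk("dRNA", TRUE))),
        unenriched = list(
          plus = one_strand("+", tss_act, pk / config$tex_enrichment,
                            mk("dRNA", FALSE)),
          minus = one_strand("-", tss_act, pk / config$tex_enrichment,
                             mk("dRNA", FALSE))))
      term[[cond]][[rep_i]] <- list(
        plus = one_strand("+", tep_act, pk, mk("Term", NA)),
        minus = one_strand("-", tep_act, pk, mk("Term", NA)))
      cov[[cond]][[rep_i]] <- list(
        plus = .sparse_pois(cov_lambda[["+"]], contig, "+",
                            mk("RNAseq-coverage", NA)),
        minus = .sparse_pois(cov_lambda[["-"]], contig, "-",
                             mk("RNAseq-coverage", NA)))
    }
  }
  list(drna = drna, term = term, cov = cov)
}

#' Sensitivity and precision of called sites against a planted truth
#'
#' @param called data.frame with `pos`, `strand`.
#' @param truth data.frame with `pos`, `strand` (planted sites).
#' @param tol matching tolerance in nt (default 5).
#' @return list(`sensitivity`, `precision`, `n_truth`, `n_called`).
#' @export
recovery_stats <- function(called, truth, tol = 5L) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    any(called$strand == truth$strand[i] &
          abs(called$pos - truth$pos[i]) <= tol)
  }, logical(1))
  hit_called <- vapply(seq_len(nrow(called)), function(i) {
    any(truth$strand == called$strand[i] &
          abs(truth$pos - called$pos[i]) <= tol)
  }, logical(1))
  list(sensitivity = mean(hit_truth), precision = mean(hit_called),
       n_truth = nrow(truth), n_called = nrow(called))
}
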