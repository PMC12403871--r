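# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fx$sim)) {
    cfg <- sim_config(seed = 1)
    s <- simulate_genome(cfg)
    .fx$sim <- list(cfg = cfg, ann = s$annotation, truth = s$truth,
                    libs = simulate_libraries(s$annotation, s$truth, cfg))
  }
  .fx$sim
}

pipeline_fixture <- function() {
  if (is.null(.fx$pipe)) {
    f <- sim_fixture()
    .fx$pipe <- run_tu_pipeline(f$ann, f$libs)
  }
  .fx$pipe
}

# single-position end profile helpers for rule-arithmetic tests
prof <- function(pos, count, strand = "+", contig = "c1",
                 meta = list(assay = "dRNA", condition = "c", replicate = 1L,
                             enriched = NA)) {
  end_profile(contig, strand, pos, count, meta)
}

# tiny annotation: one contig of random sequence with the given gene table
tiny_annotation <- function(genes, len = 3000L, seed = 99L) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  seqs <- Biostrings::DNAStringSet(s)
  names(seqs) <- "c1"
  genome_annotation(seqs, genes)
}

gene_row <- function(gene_id, start, end, strand, cog = NA_character_) {
  data.frame(gene_id = gene_id, contig_id = "c1", start = start, end = end,
             strand = strand, cog = cog, stringsAsFactors = FALSE)
}
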