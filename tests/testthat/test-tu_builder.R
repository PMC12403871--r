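make_tss <- function(pos, strand = "+", category = "P", gene = NA,
                     conditions = "NMS", height = 100, utr5 = NA) {
  data.frame(pos = pos, strand = strand, category = category, gene = gene,
             conditions = conditions, height = height, utr5 = utr5,
             stringsAsFactors = FALSE)
}
make_tep <- function(pos, strand = "+", category = "P",
                     conditions = "NMS", height = 50) {
  data.frame(pos = pos, strand = strand, category = category,
             conditions = conditions, height = height,
             stringsAsFactors = FALSE)
}

test_that("TSS-TEP pairing builds mono-, poly- and gene-less TUs", {
  ann <- tiny_annotation(gene_row("g1", 1000L, 2000L, "+"))
  tus <- assemble_tus(make_tss(950L, gene = "g1"), make_tep(2100L), ann)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$category, "monocistronic")
  expect_equal(tus$genes, "g1")

  ann2 <- tiny_annotation(rbind(gene_row("g1", 1000L, 1400L, "+"),
                                gene_row("g2", 1450L, 2000L, "+")))
  tus2 <- assemble_tus(make_tss(950L, gene = "g1"), make_tep(2100L), ann2)
  expect_equal(tus2$category, "polycistronic")
  expect_equal(tus2$n_genes, 2L)
  expect_equal(tus2$genes, "g1,g2")

  # cis-regulatory TU: TSS paired with a C-class TEP inside its own 5'-UTR
  tus3 <- assemble_tus(make_tss(937L, gene = "g1", utr5 = 63L),
                       make_tep(980L, category = "C"),
                       tiny_annotation(gene_row("g1", 1000L, 2000L, "+")))
  expect_equal(tus3$category, "cis_regulatory")
  expect_equal(tus3$n_genes, 0L)

  tus4 <- assemble_tus(make_tss(2500L, category = "N"),
                       make_tep(2800L, category = "N"),
                       tiny_annotation(gene_row("g1", 1000L, 2000L, "+")))
  expect_equal(tus4$category, "intergenic")
})

test_that("pairing respects the span cap and the next gene block", {
  ann <- tiny_annotation(rbind(gene_row("g1", 1000L, 1500L, "+"),
                               gene_row("g2", 2500L, 2900L, "+")),
                         len = 20000L)
  tss <- rbind(make_tss(950L, gene = "g1"),
               make_tss(2450L, gene = "g2"))
  # only TEP lies beyond g2's start: g1's TSS must not pair across it
  tep <- make_tep(2950L)
  tus <- assemble_tus(tss, tep, ann)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$tss_pos, 2450L)

  # span cap
  far <- assemble_tus(make_tss(100L, category = "N"),
                      make_tep(19000L, category = "N"), ann,
                      max_span = 15000L)
  expect_equal(nrow(far), 0L)
})

test_that("per-condition TUs merge when endpoints agree within 5 nt", {
  ann <- tiny_annotation(gene_row("g1", 1000L, 2000L, "+"))
  tss <- make_tss(950L, gene = "g1", conditions = "NMS,ANMS")
  tep <- make_tep(2100L, conditions = "NMS,ANMS")
  tus <- assemble_tus(tss, tep, ann, conditions = c("NMS", "ANMS"))
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$conditions, "NMS,ANMS")
})

test_that("TU categories partition and the poly median is as defined", {
  tus <- data.frame(category = c("monocistronic", "polycistronic",
                                 "polycistronic", "polycistronic",
                                 "cis_regulatory"),
                    n_genes = c(1L, 2L, 3L, 5L, 0L))
  s <- categorize_and_summarize(tus)
  expect_equal(unname(s$counts),c(1L, 3L, 1L, 0L))
  expect_equal(sum(s$counts), nrow(tus))
  expect_equal(s$median_genes_polycistronic, 3)
})

test_that("the functional enrichment score follows the literal formula", {
  expect_equal(functional_enrichment_score(c("M", "M", "D"))$score, 1)
  expect_equal(functional_enrichment_score(c("C", "C", "C"))$score, 3)
  expect_equal(functional_enrichment_score(c("M", "D", "N"))$score, 1 / 3,
               tolerance = 1e-12)
  expect_equal(functional_enrichment_score(c("C", "C", "C"),
                                           mode = "per_gene")$score, 1)
  none <- functional_enrichment_score(c(NA, NA))
  expect_true(is.na(none$score))
  expect_equal(none$n_genes_with_cog, 0L)
  # unassigned genes are excluded, not counted in the denominator
  expect_equal(functional_enrichment_score(c("M", "M", NA))$score, 2)
})

test_that("the random-neighbor baseline is deterministic and calibrated", {
  ann <- tiny_annotation(do.call(rbind, lapply(1:12, function(i) {
    gene_row(sprintf("g%02d", i), i * 200L, i * 200L + 150L, "+",
             cog = sample(c("M", "C", "D"), 1))
  })), len = 5000L, seed = 42L)
  b1 <- random_neighbor_baseline(ann, tu_sizes = c(2L, 3L), n_draws = 50L,
                                 seed = 9)
  b2 <- random_neighbor_baseline(ann, tu_sizes = c(2L, 3L), n_draws = 50L,
                                 seed = 9)
  expect_identical(b1$scores, b2$scores)

  # identical observed and baseline score sets: p ~ 1
  same <- random_neighbor_baseline(ann, tu_sizes = 2L, n_draws = 30L,
                                   seed = 9, observed_scores = NULL)
  p <- random_neighbor_baseline(ann, tu_sizes = 2L, n_draws = 30L,
                                seed = 9, observed_scores = same$scores)
  expect_gt(p$p_value, 0.95)
})

test_that("planted operons score above the random-neighbor baseline", {
  cfg <- sim_config(genome_length = 8e5L, n_genes = 330L,
                    operon_sizes = 2:4, seed = 7)
  s <- simulate_genome(cfg)
  poly <- s$truth$operons[s$truth$operons$n_genes >= 2, ]
  expect_gte(nrow(poly), 100L)
  g <- s$annotation$genes
  obs <- vapply(strsplit(poly$gene_ids, ","), function(gid) {
    functional_enrichment_score(g$cog[match(gid, g$gene_id)])$score
  }, numeric(1))
  bl <- random_neighbor_baseline(s$annotation, poly$n_genes,
                                 n_draws = 300L, seed = 7,
                                 observed_scores = obs)
  expect_gt(stats::median(obs), stats::median(bl$scores))
  expect_lt(bl$p_value, 0.01)
})

test_that("assembled TU spans contain their genes on the fixture", {
  f <- pipeline_fixture()
  sim <- sim_fixture()
  g <- sim$ann$genes
  for (i in seq_len(nrow(f$tus))) {
    gid <- strsplit(f$tus$genes[i], ",")[[1]]
    gid <- gid[nzchar(gid)]
    if (!length(gid)) next
    sel <- g[match(gid, g$gene_id), ]
    expect_true(all(sel$start >= f$tus$span_start[i]))
    expect_true(all(sel$end <= f$tus$span_end[i]))
    expect_true(all(sel$strand == f$tus$strand[i]))
  }
  s <- categorize_and_summarize(f$tus)
  expect_equal(sum(s$counts), nrow(f$tus))
})
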