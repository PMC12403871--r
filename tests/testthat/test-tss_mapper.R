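test_that("the TSS calling rule applies height, enrichment and local maxima", {
  enr <- prof(100L, 20)
  une <- prof(100L, 5)
  got <- call_tss(enr, une)
  expect_equal(got$pos, 100L)  # ratio (20+1)/(5+1) = 3.5 >= 2
  expect_equal(got$enrichment, 3.5)

  # (20+1)/(15+1) < 2: rejected
  expect_equal(nrow(call_tss(prof(100L, 20), prof(100L, 15))), 0L)
  # below min_height
  expect_equal(nrow(call_tss(prof(100L, 9), prof(100L, 0))), 0L)

  # local maximum within +/-2; tie kept at the 5'-most position
  enr2 <- prof(c(100L, 101L), c(20, 20))
  got2 <- call_tss(enr2, prof(c(100L, 101L), c(1, 1)))
  expect_equal(got2$pos, 100L)
  enr2m <- prof(c(100L, 101L), c(20, 20), strand = "-")
  got2m <- call_tss(enr2m, prof(c(100L, 101L), c(1, 1), strand = "-"))
  expect_equal(got2m$pos, 101L)  # 5'-most on the minus strand

  expect_error(call_tss(prof(1L, 20), prof(1L, 1, strand = "-")), "strand")
})

test_that("sites merge within 5 nt by single linkage with condition union", {
  two <- list(
    NMS = data.frame(pos = 100L, strand = "+", height = 50),
    ANMS = data.frame(pos = 104L, strand = "+", height = 30))
  m <- merge_sites(two)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 100L)  # higher summed height wins
  expect_equal(m$conditions, "NMS,ANMS")
  expect_true(m$constitutive)

  apart <- list(
    NMS = data.frame(pos = 100L, strand = "+", height = 50),
    ANMS = data.frame(pos = 106L, strand = "+", height = 30))
  expect_equal(nrow(merge_sites(apart)), 2L)

  # chain 100,105,110 links into one cluster; representative = max height
  chain <- list(NMS = data.frame(pos = c(100L, 105L, 110L), strand = "+",
                                 height = c(10, 80, 20)))
  mc <- merge_sites(chain)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$pos, 105L)
})

test_that("merging a merged site list is idempotent", {
  set.seed(33)
  sites <- data.frame(pos = sort(sample(1:2000, 60)),
                      strand = sample(c("+", "-"), 60, TRUE),
                      height = rpois(60, 40))
  m1 <- merge_sites(list(NMS = sites))
  m2 <- merge_sites(list(NMS = m1[, c("pos", "strand", "height")]))
  expect_equal(m2$pos, m1$pos)
  expect_equal(m2$strand, m1$strand)
})

test_that("TSS categories follow the P/S/I/A/N precedence", {
  ann <- tiny_annotation(gene_row("g1", 1000L, 2000L, "+"))
  sites <- data.frame(
    pos = c(950L, 940L, 1500L, 1500L, 2500L),
    strand = c("+", "+", "-", "+", "+"),
    height = c(100, 40, 30, 25, 12),
    conditions = "NMS", stringsAsFactors = FALSE)
  cl <- classify_tss(sites, ann)
  expect_equal(cl$category, c("P", "S", "A", "I", "N"))
  expect_equal(cl$gene[1:2], c("g1", "g1"))
  # partition: every site got exactly one category
  expect_false(anyNA(cl$category))
  expect_equal(sum(table(cl$category)), nrow(sites))
})

test_that("a shared upstream site goes to the nearer gene start", {
  ann <- tiny_annotation(rbind(gene_row("g1", 1000L, 1400L, "+"),
                               gene_row("g2", 1500L, 2000L, "+")))
  # site 1450: upstream of g2 by 50; inside no gene; competes only for g2
  sites <- data.frame(pos = c(950L, 1450L), strand = "+",
                      height = c(50, 60), conditions = "NMS")
  cl <- classify_tss(sites, ann)
  expect_equal(cl$gene, c("g1", "g2"))
  expect_equal(cl$category, c("P", "P"))
})

test_that("5'-UTR lengths and the leaderless boundary are computed strictly", {
  ann <- tiny_annotation(gene_row("g1", 1000L, 2000L, "+"))
  sites <- data.frame(pos = c(937L, 990L), strand = "+",
                      height = c(90, 20), conditions = "NMS")
  cl <- classify_tss(sites, ann)
  res <- utr5_and_leaderless(cl, ann)
  expect_equal(res$records$utr5[res$records$category == "P"], 63L)
  expect_equal(res$records$utr5[res$records$category == "S"], 10L)
  # boundary: utr5 == 10 with leaderless_max = 10 is NOT leaderless
  expect_false(res$records$leaderless[res$records$category == "S"])
  res2 <- utr5_and_leaderless(cl, ann, leaderless_max = 11L)
  expect_true(res2$records$leaderless[res2$records$category == "S"])
  expect_equal(res$summary$median, 36.5)
})

test_that("minus-strand UTR arithmetic mirrors the plus strand", {
  ann <- tiny_annotation(gene_row("g1", 1000L, 2000L, "-"))
  sites <- data.frame(pos = 2062L, strand = "-", height = 50,
                      conditions = "NMS")
  cl <- classify_tss(sites, ann)
  expect_equal(cl$category, "P")
  res <- utr5_and_leaderless(cl, ann)
  expect_equal(res$records$utr5, 63L)  # 2062 - (2000 - 1) = 63
})

test_that("base composition rows are frequencies oriented by transcription", {
  seqs <- Biostrings::DNAStringSet(paste0(strrep("T", 50), "G", strrep("T", 50)))
  names(seqs) <- "c1"
  sites <- data.frame(pos = 50L, strand = "+")
  bc <- base_composition(sites, seqs, flank = 2)
  expect_equal(dim(bc), c(5L, 4L))
  expect_equal(unname(bc["0", "G"]), 1)
  expect_true(all(abs(rowSums(bc) - 1) < 1e-9))
  # minus strand: reverse complement puts A at the site row
  bcm <- base_composition(data.frame(pos = 50L, strand = "-"), seqs, flank = 2)
  expect_equal(unname(bcm["0", "C"]), 1)
  expect_error(base_composition(sites[0, ], seqs), "empty")
})

test_that("a planted +1 purine bias is recovered from simulated TSSs", {
  cfg <- sim_config(genome_length = 4e5L, n_genes = 250L,
                    purine_bias = 0.9, seed = 3)
  s <- simulate_genome(cfg)
  bc <- base_composition(s$truth$tss, s$annotation, flank = 2)
  purine <- sum(bc["0", c("A", "G")])
  expect_gt(purine, 0.87)
  expect_lt(purine, 0.93)
})

test_that("calling is symmetric under strand mirroring", {
  f <- sim_fixture()
  L <- f$cfg$genome_length
  enr <- profile_sum(list(f$libs$drna$NMS[[1]]$enriched$plus,
                          f$libs$drna$NMS[[2]]$enriched$plus))
  une <- profile_sum(list(f$libs$drna$NMS[[1]]$unenriched$plus,
                          f$libs$drna$NMS[[2]]$unenriched$plus))
  fwd <- call_tss(enr, une)
  mirror <- function(p) end_profile(p$contig, "-", L - 1L - p$pos, p$count,
                                    p$meta)
  rev <- call_tss(mirror(enr), mirror(une))
  expect_equal(sort(L - 1L - rev$pos), sort(fwd$pos))
})
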