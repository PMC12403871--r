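test_that("the HS/LS split is inclusive at the threshold", {
  rec <- data.frame(pos = 1:2, strand = "+", delta_g = c(-19, -10))
  out <- split_hs_ls(rec, threshold = -19)
  expect_equal(out$records$structure_class, c("HS", "LS"))
})

test_that("median thresholding splits as the data median dictates", {
  rec <- data.frame(pos = 1:4, strand = "+",
                    delta_g = c(-30, -20, -10, -5))
  out <- split_hs_ls(rec, threshold = "median")
  expect_equal(out$threshold_used, -15)
  expect_equal(out$records$structure_class, c("HS", "HS", "LS", "LS"))

  # odd n: <= inclusivity puts ceiling(n/2) sites in HS
  odd <- data.frame(pos = 1:5, strand = "+",
                    delta_g = c(-25, -18, -12, -7, -3))
  o <- split_hs_ls(odd, threshold = "median")
  expect_equal(sum(o$records$structure_class == "HS"), 3L)
  expect_error(split_hs_ls(rec[0, ]), "empty")
})

test_that("U-content typing counts the tract 3' of the stem", {
  mk_ann <- function(tract) {
    s <- paste0(strrep("G", 100), tract, strrep("G", 100))
    seqs <- Biostrings::DNAStringSet(s); names(seqs) <- "c1"
    seqs
  }
  rec <- data.frame(pos = 120L, strand = "+", structure_class = "HS",
                    stem_close_genomic = 99L, stringsAsFactors = FALSE)
  r1 <- type_u_content(rec, mk_ann("TTTAGCACGA"))
  expect_equal(r1$u_count, 3L)
  expect_equal(r1$shape, "HS_U_RICH")
  r2 <- type_u_content(rec, mk_ann("GCGCGCGCGC"))
  expect_equal(r2$u_count, 0L)
  expect_equal(r2$shape, "HS_U_LACK")
  r3 <- type_u_content(rec, mk_ann("TTAGGGGGGG"))
  expect_equal(r3$u_count, 2L)  # boundary: 2 < 3
  expect_equal(r3$shape, "HS_U_LACK")

  ls <- rec; ls$structure_class <- "LS"
  expect_equal(type_u_content(ls, mk_ann("TTTTTTTTTT"))$shape, "LS")

  broken <- rec; broken$stem_close_genomic <- NA_integer_
  expect_error(type_u_content(broken, mk_ann("TTTAGCACGA")), "hairpin")
})

test_that("readthrough fractions are downstream/upstream coverage ratios", {
  cov <- list(
    plus = end_profile("c1", "+", 0:999,
                       c(rep(10, 500), rep(2, 500))),
    minus = NULL)
  rec <- data.frame(pos = 499L, strand = "+")
  out <- readthrough_fraction(rec, cov)
  expect_equal(out$records$readthrough, 0.2)

  flat <- list(plus = end_profile("c1", "+", 0:999, rep(7, 1000)))
  expect_equal(readthrough_fraction(rec, flat)$records$readthrough, 1)

  # zero upstream coverage: undefined, excluded and counted
  zero <- list(plus = end_profile("c1", "+", 600:999, rep(5, 400)))
  z <- readthrough_fraction(rec, zero)
  expect_true(is.na(z$records$readthrough))
  expect_equal(z$n_undefined, 1L)
})

test_that("planted terminator classes order their readthrough medians", {
  f <- pipeline_fixture()
  s <- f$readthrough$summary
  med <- setNames(s$median_readthrough, s$class)
  expect_lt(med["HS_U_RICH"], med["HS_U_LACK"])
  expect_lt(med["HS_U_LACK"], med["LS"])
  rt <- f$tep$readthrough
  w <- stats::wilcox.test(rt[f$tep$shape == "HS_U_RICH"],
                          rt[f$tep$shape == "HS_U_LACK"], exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("shape accounting partitions the folded TEP set", {
  f <- pipeline_fixture()
  tab <- table(f$tep$shape)
  hs <- sum(f$tep$structure_class == "HS")
  expect_equal(unname(tab["HS_U_RICH"] + tab["HS_U_LACK"]), hs)
  expect_equal(sum(tab), nrow(f$tep))
  expect_true(all(f$tep$u_count[f$tep$structure_class == "HS"] >= 0))
  expect_true(all(f$tep$u_count[f$tep$structure_class == "HS"] <= 10))
})

test_that("positional enrichment recovers the planted U-tract of L terminators", {
  f <- pipeline_fixture()
  sim <- sim_fixture()
  pe <- positional_enrichment(f$tep, sim$ann, flank = 50)
  m <- pe[["HS_U_RICH"]]
  expect_equal(dim(m), c(101L, 4L))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  # mean U frequency near the TEP exceeds the genomic background (17.5%)
  near <- as.character(-5:5)
  expect_gt(mean(m[near, "T"]), 0.175)
})

test_that("stem/loop metrics compare classes and parse planted hairpins", {
  f <- pipeline_fixture()
  sl <- stem_loop_metrics(f$tep)
  expect_true(all(c("HS_U_RICH", "HS_U_LACK") %in% names(sl$distributions)))
  # planted stems are 8-12 bp; folded stems must be in that neighbourhood
  hs_stems <- c(sl$distributions$HS_U_RICH$stem, sl$distributions$HS_U_LACK$stem)
  expect_gte(min(hs_stems), 6L)
  expect_true(!is.null(sl$comparisons))
  expect_true(all(c("U", "p_value") %in% names(sl$comparisons)))
})
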