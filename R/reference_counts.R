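# Published transcriptome-architecture summary for Methylocystis sporium 5.

#' Published site and TU counts for the M. sporium 5 transcriptome map
#'
#' The per-class counts and percentages reported for the dRNA-seq /
#' Term-seq transcriptome architecture of \emph{Methylocystis sporium} 5:
#' TSS and TEP category breakdowns, condition specificity (NMS = nitrate
#' mineral salts, ANMS = ammonium mineral salts medium), the structural
#' split of TEPs, and TU categories. Used for arithmetic-consistency
#' checks; these figures are not recomputable from the synthetic data.
#'
#' @return nested list with elements `tss`, `tep`, `tu`.
#' @export
msporium_reference_counts <- function() {
  list(
    tss = list(
      total = 1983L,
      categories = c(P = 1700L, S = 108L, I = 28L, A = 83L, N = 64L),
      primary_percent = 85.7,
      conditions = c(constitutive = 1496L, NMS = 281L, ANMS = 206L),
      condition_percent = c(constitutive = 75.4, NMS = 14.2, ANMS = 10.4),
      median_utr5 = 63,
      n_leaderless = 88L,
      leadered_percent = 92
    ),
    tep = list(
      total = 1483L,
      categories = c(P = 1137L, S = 148L, C = 62L, A = 55L, N = 81L),
      primary_percent = 76.7,
      conditions = c(shared = 806L, NMS = 420L, ANMS = 257L),
      condition_percent = c(shared = 54.3, NMS = 28.3, ANMS = 17.3),
      hs = 772L, ls = 711L,
      hs_u_rich = 170L, hs_u_lack = 602L,
      dg_threshold = -19,
      median_dg_tep = -19.3, median_dg_random = -13.2,
      median_utr3 = 89, modal_utr3_bin = c(50, 59),
      short_utr3_percent = 3.2
    ),
    tu = list(
      total = 1431L,
      categories = c(monocistronic = 771L, polycistronic = 551L,
                     cis_regulatory = 71L, intergenic = 38L),
      median_genes_polycistronic = 3.0
    )
  )
}
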