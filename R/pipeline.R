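# End-to-end pipeline: from end-count tracks to a classified TU map.

#' Run the full transcription-unit mapping pipeline
#'
#' Pools replicates per condition, calls TSSs (dRNA-seq enrichment rule)
#' and TEPs (Term-seq local maxima) per strand and condition, merges sites
#' within +/- `merge_window` nt across conditions, classifies both site
#' types against the annotation, folds TEP upstream windows and types
#' terminator shapes, computes readthrough fractions from RNA-seq
#' coverage, and assembles transcription units.
#'
#' @param annotation a `genome_annotation`.
#' @param libs library set as produced by [simulate_libraries()] (or an
#'   equally shaped list read from bedGraph files).
#' @param min_height,min_enrichment TSS calling thresholds.
#' @param tep_min_height TEP calling threshold.
#' @param merge_window cross-condition merge half-width, nt.
#' @param hs_threshold delta G threshold for the HS/LS split (`"median"`
#'   or kcal/mol).
#' @param readthrough_condition condition whose pooled RNA-seq coverage is
#'   used for readthrough (default: first condition).
#' @param temperature folding temperature, degrees Celsius.
#' @param max_span maximum TU span, nt.
#' @return list with `tss` (classified records), `tss_summary`, `tep`
#'   (classified, folded, shaped records with readthrough), `tep_summary`,
#'   `hs_threshold_used`, `readthrough`, `tus`, `tu_summary`.
#' @export
run_tu_pipeline <- function(annotation, libs, min_height = 10,
                            min_enrichment = 2, tep_min_height = 10,
                            merge_window = 5L, hs_threshold = "median",
                            readthrough_condition = NULL,
                            temperature = 30, max_span = 15000L) {
  conds <- names(libs$drna)
  pool <- function(assay_cond, part = NULL) {
    # assay_cond: list over replicates; part: "enriched"/"unenriched" or NULL
    lapply(c(plus = "plus", minus = "minus"), function(s) {
      profs <- lapply(assay_cond, function(rep_lib) {
        if (is.null(part)) rep_lib[[s]] else rep_lib[[part]][[s]]
      })
      profile_sum(profs)
    })
  }

  tss_by_cond <- list(); tep_by_cond <- list()
  for (cond in conds) {
    enr <- pool(libs$drna[[cond]], "enriched")
    une <- pool(libs$drna[[cond]], "unenriched")
    tss_by_cond[[cond]] <- rbind(
      call_tss(enr$plus, une$plus, min_height, min_enrichment),
      call_tss(enr$minus, une$minus, min_height, min_enrichment))
    tm <- pool(libs$term[[cond]])
    tep_by_cond[[cond]] <- rbind(
      call_tep(tm$plus, tep_min_height),
      call_tep(tm$minus, tep_min_height))
  }

  tss <- merge_sites(tss_by_cond, window = merge_window, tie = "five_prime")
  tss <- classify_tss(tss, annotation)
  tss_res <- utr5_and_leaderless(tss, annotation)
  tss <- tss_res$records

  tep <- merge_sites(tep_by_cond, window = merge_window, tie = "three_prime")
  tep <- classify_tep(tep, annotation, tss)
  tep_res <- utr3_lengths(tep)

  tep <- fold_teps(tep, annotation, temperature = temperature)
  hs <- split_hs_ls(tep, threshold = hs_threshold)
  tep <- type_u_content(hs$records, annotation)

  rt_cond <- readthrough_condition %||% conds[1L]
  cov <- pool(libs$cov[[rt_cond]])
  rt <- readthrough_fraction(tep, cov)
  tep <- rt$records

  tus <- assemble_tus(tss, tep, annotation, max_span = max_span,
                      merge_window = merge_window, conditions = conds)

  list(tss = tss, tss_summary = tss_res$summary,
       tep = tep, tep_summary = tep_res$summary,
       hs_threshold_used = hs$threshold_used,
       readthrough = rt, tus = tus,
       tu_summary = categorize_and_summarize(tus))
}
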