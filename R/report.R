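# Combined genome report: one row per genome with the headline columns used
# in comparative tables (ORF count / genome size / A+T content).

#' Summarise one or more annotated genomes as a report table
#'
#' @param records A [genome_record()] or list of them.
#' @param orfsets Matching ORF tibble, or list of them (defaults to each
#'   record's own features).
#' @param tsv,txt Optional output paths for a TSV table and a human-readable
#'   text report.
#' @return Tibble with one row per genome: `id`, `n_orfs`, `length_bp`,
#'   `at_pct`, `coding_pct_sum`, `coding_pct_union`, `n_fwd`, `n_rev`,
#'   `n_minimal_overlaps`.
#' @export
genome_report <- function(records, orfsets = NULL, tsv = NULL, txt = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!is.null(orfsets) && is.data.frame(orfsets)) orfsets <- list(orfsets)
  rows <- purrr::map_dfr(seq_along(records), function(i) {
    rec <- records[[i]]
    orfs <- if (is.null(orfsets)) rec$features else orfsets[[i]]
    genome_stats(rec, orfs)
  })
  out <- rows[, c("id", "n_orfs", "length_bp", "at_pct", "coding_pct_sum",
                  "coding_pct_union", "n_fwd", "n_rev", "n_minimal_overlaps")]
  if (!is.null(tsv)) {
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(txt)) {
    lines <- c("Genome report (ORFs / size bp / A+T %)",
               sprintf("  %s\t%d / %s / %.1f", out$id, out$n_orfs,
                       format(out$length_bp, big.mark = ","), out$at_pct))
    writeLines(lines, txt)
  }
  out
}
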