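#' Run the full annotation pipeline and write its artifacts
#'
#' Chains intergenic extraction, promoter and terminator calling, unit
#' segmentation, punctuation maturation and 5' UTR measurement, writing all
#' artifacts into `outdir`:
#' * `intergenic.tsv` -- region table (1-based inclusive coordinates, length,
#'   overlap, AT%)
#' * `signals.gff3` -- promoter, TSS and terminator calls
#' * `units.gff3` -- transcription units and mature transcripts
#' * `units_report.txt` -- human-readable unit table
#' * `utr5.tsv` -- 5' UTRs of mRNA-first units
#' * `summary.json` -- machine-readable counts (genes, intergenic totals,
#'   AT%, promoter regions, units, max terminator distance)
#' * `config.json` -- parameter echo for provenance
#'
#' Outputs are deterministic: running twice on identical inputs gives
#' byte-identical artifacts.
#'
#' @param genome A [circular_genome] or path to a single-record FASTA.
#' @param annot An annotation tibble or path to a GFF3 file.
#' @param outdir Output directory (created if missing).
#' @param motif Promoter motif (IUPAC or PWM); default the Hypocreales
#'   consensus.
#' @param max_mismatch IUPAC promoter-scan mismatch tolerance.
#' @param threshold_frac PWM promoter-scan threshold.
#' @param term_motif Terminator motif (default TAAATT).
#' @param window_nt Terminator search window.
#' @return The summary list, invisibly.
#' @export
run_annotate_pipeline <- function(genome, annot, outdir,
                                  motif = motif_presets()$hypocreales,
                                  max_mismatch = 0L, threshold_frac = 0.8,
                                  term_motif = motif_presets()$terminator,
                                  window_nt = 250L) {
  if (is.character(genome)) genome <- read_genome(genome, format = "fasta")
  if (is.character(annot)) {
    annot <- read_annotation(annot, format = "gff3",
                             genome_length = genome$length)
  }
  if (is.null(attr(annot, "genome_length"))) {
    attr(annot, "genome_length") <- genome$length
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  regions <- extract_intergenic(genome, annot)
  promoters <- find_promoters(genome, annot, motif = motif,
                              max_mismatch = max_mismatch,
                              threshold_frac = threshold_frac)
  terminators <- find_terminators(genome, annot, term_motif = term_motif,
                                  window_nt = window_nt)
  units <- segment_units(annot, promoters, terminators)
  mature <- mature_transcripts(units, annot)
  first_kinds <- annot$kind[match(purrr::map_chr(units$genes, 1), annot$name)]
  utr <- utr5_length(units[first_kinds == "mRNA", ], annot)

  reg_out <- dplyr::mutate(
    regions,
    region = paste0(.data$upstream_gene, "-", .data$downstream_gene),
    start = .data$start + 1L,
    at_pct = purrr::map_dbl(.data$sequence, function(s) {
      if (nchar(s) == 0) NA_real_ else composition(s)$at_pct
    })
  )
  write.table(
    dplyr::select(reg_out, "region", "start", "end", "length", "overlap_bp",
                  "at_pct"),
    file.path(outdir, "intergenic.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  motif_len <- if (inherits(motif, "pwm")) motif$length else motif$length
  write_calls_gff3(promoters, terminators,
                   file.path(outdir, "signals.gff3"),
                   motif_length = motif_len,
                   term_length = term_motif$length, seqid = genome$id)
  write_units_gff3(units, mature, file.path(outdir, "units.gff3"),
                   seqid = genome$id)
  unit_report(units, file.path(outdir, "units_report.txt"))
  write.table(utr, file.path(outdir, "utr5.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  comp <- composition(genome)
  ig_seq <- paste(regions$sequence, collapse = "")
  summary <- list(
    genome_id = genome$id,
    genome_length = genome$length,
    n_genes = nrow(annot),
    gc_pct = round(comp$gc_pct, 1),
    at_pct_genome = round(comp$at_pct, 1),
    at_pct_intergenic = if (nchar(ig_seq)) round(composition(ig_seq)$at_pct, 1)
                        else NA,
    intergenic_total_bp = sum(regions$length),
    largest_intergenic_bp = max(regions$length),
    n_overlaps = sum(regions$overlap_bp > 0),
    n_promoter_regions = nrow(promoters),
    n_terminators = nrow(terminators),
    max_terminator_distance = if (nrow(terminators)) max(terminators$distance_nt)
                              else NA,
    n_units = nrow(units)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(motif = if (inherits(motif, "pwm")) "pwm" else motif$symbols,
         max_mismatch = max_mismatch, threshold_frac = threshold_frac,
         term_motif = term_motif$symbols, window_nt = window_nt),
    file.path(outdir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
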