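#' Call promoters in intergenic regions
#'
#' Scans the sense strand of every intergenic region with a degenerate IUPAC
#' consensus or a PWM. When a region holds several hits, the hit closest to
#' the downstream gene's start is retained (mitochondrial promoters sit just
#' upstream of the first gene of their transcription unit). The transcription
#' start site (`tss`, the "+1" base) is the base immediately 3' of the motif.
#'
#' @param genome A [circular_genome].
#' @param annotation Annotation tibble.
#' @param motif An [iupac_motif] (default: the Hypocreales consensus
#'   `WTAGWWHWWHD`) or a [build_pwm] object.
#' @param max_mismatch Mismatch tolerance for IUPAC scanning (default 0).
#' @param threshold_frac Score threshold fraction for PWM scanning
#'   (default 0.8).
#' @return A tibble of promoter calls in circle order: `upstream_gene`,
#'   `downstream_gene`, `position` (genome coordinate of the motif start),
#'   `strand`, `matched`, `mismatches`, `score`, `tss`.
#' @export
find_promoters <- function(genome, annotation,
                           motif = motif_presets()$hypocreales,
                           max_mismatch = 0L, threshold_frac = 0.8) {
  regions <- extract_intergenic(genome, annotation)
  if (nrow(regions) == 0L) abort("no intergenic regions to scan")
  L <- genome$length
  motif_len <- if (inherits(motif, "pwm")) motif$length else {
    if (is.character(motif)) motif <- iupac_motif(motif)
    motif$length
  }
  calls <- purrr::pmap(regions, function(upstream_gene, downstream_gene,
                                         start, end, length, overlap_bp,
                                         sequence) {
    if (length < motif_len) return(NULL)
    hits <- if (inherits(motif, "pwm")) {
      scan_pwm(motif, sequence, threshold_frac = threshold_frac)
    } else {
      scan_iupac(motif, sequence, max_mismatch = max_mismatch,
                 strands = "sense")
    }
    if (nrow(hits) == 0L) return(NULL)
    hit <- hits[which.max(hits$position), ]   # closest to downstream gene
    tibble(
      upstream_gene = upstream_gene,
      downstream_gene = downstream_gene,
      position = (start + hit$position) %% L,
      strand = "+",
      matched = hit$matched,
      mismatches = hit$mismatches,
      score = hit$score,
      tss = (start + hit$position + motif_len) %% L
    )
  })
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0L) {
    inform("no promoter motif hit in any intergenic region")
    return(tibble(upstream_gene = character(), downstream_gene = character(),
                  position = integer(), strand = character(),
                  matched = character(), mismatches = integer(),
                  score = double(), tss = integer()))
  }
  dplyr::arrange(out, .data$position)
}

#' Call terminator motifs downstream of mRNA and rRNA genes
#'
#' For each top-level mRNA or rRNA feature, searches the sense strand from
#' the base after the coding 3' end through `window_nt` bases for the
#' terminator motif (default the 5'-TAAATT-3' hexamer) and reports the
#' nearest hit, at most one call per feature. `distance_nt` counts the bases
#' between the coding end and the motif start (0 = abutting). tRNA genes are
#' never scanned: their 3' ends are punctuation processing sites, not
#' termination signals.
#'
#' @param genome A [circular_genome].
#' @param annotation Annotation tibble.
#' @param term_motif An [iupac_motif]; must be at least 4 nt.
#' @param window_nt Search window in nt downstream of the coding end
#'   (default 250, covering the 1-218 nt range observed in entomopathogenic
#'   fungal mitogenomes with margin).
#' @return A tibble of calls: `feature`, `kind`, `position` (genome
#'   coordinate of the motif start on the forward strand), `strand`,
#'   `distance_nt`, `matched`.
#' @export
find_terminators <- function(genome, annotation,
                             term_motif = motif_presets()$terminator,
                             window_nt = 250L) {
  if (is.character(term_motif)) term_motif <- iupac_motif(term_motif)
  if (term_motif$length < 4L) abort("terminator motif must be at least 4 nt")
  if (window_nt < term_motif$length) {
    abort("window_nt must be at least the motif length")
  }
  L <- genome$length
  targets <- dplyr::filter(annotation, is.na(.data$parent),
                           .data$kind %in% c("mRNA", "rRNA"))
  calls <- purrr::pmap(targets, function(name, kind, start, end, strand,
                                         parent, ...) {
    if (strand == "+") {
      win <- .circ_substr(genome$sequence, end, (end + window_nt) %% L)
      hits <- scan_iupac(term_motif, win, max_mismatch = 0L)
      if (nrow(hits) == 0L) return(NULL)
      d <- min(hits$position)
      pos <- (end + d) %% L
      matched <- hits$matched[which.min(hits$position)]
    } else {
      # downstream of a minus-strand gene = before its forward-strand start
      win <- revcomp(.circ_substr(genome$sequence,
                                  (start - window_nt) %% L, start))
      hits <- scan_iupac(term_motif, win, max_mismatch = 0L)
      if (nrow(hits) == 0L) return(NULL)
      d <- min(hits$position)
      pos <- (start - d - term_motif$length) %% L
      matched <- hits$matched[which.min(hits$position)]
    }
    tibble(feature = name, kind = kind, position = pos, strand = strand,
           distance_nt = d, matched = matched)
  })
  out <- dplyr::bind_rows(calls)
  if (nrow(out) == 0L) {
    return(tibble(feature = character(), kind = character(),
                  position = integer(), strand = character(),
                  distance_nt = integer(), matched = character()))
  }
  dplyr::arrange(out, .data$position)
}

#' Export promoter/terminator calls and TSSs as GFF3
#'
#' Writes promoter, TSS and terminator features (1-based inclusive
#' coordinates) to a single GFF3 file.
#'
#' @param promoters Tibble from [find_promoters] (or `NULL`).
#' @param terminators Tibble from [find_terminators] (or `NULL`).
#' @param path Output path.
#' @param motif_length Promoter motif length (used for the promoter span).
#' @param term_length Terminator motif length.
#' @param seqid Sequence identifier.
#' @export
write_calls_gff3 <- function(promoters = NULL, terminators = NULL, path,
                             motif_length = 11L, term_length = 6L,
                             seqid = "genome") {
  rows <- character()
  gff_row <- function(type, start0, len, strand, id) {
    sprintf("%s\tmitotrx\t%s\t%d\t%d\t.\t%s\t.\tID=%s", seqid, type,
            start0 + 1L, start0 + len, strand, id)
  }
  if (!is.null(promoters) && nrow(promoters)) {
    rows <- c(rows,
      unlist(purrr::pmap(promoters, function(downstream_gene, position, tss,
                                             strand, ...) {
        c(gff_row("promoter", position, motif_length, strand,
                  paste0("promoter_", downstream_gene)),
          gff_row("TSS", tss, 1L, strand, paste0("tss_", downstream_gene)))
      })))
  }
  if (!is.null(terminators) && nrow(terminators)) {
    rows <- c(rows,
      unlist(purrr::pmap(terminators, function(feature, position, strand, ...) {
        gff_row("terminator", position, term_length, strand,
                paste0("terminator_", feature))
      })))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
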