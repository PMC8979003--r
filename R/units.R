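#' Segment an annotated circle into polycistronic transcription units
#'
#' Each unit begins at a promoter's "+1" transcription start site (tss) and
#' contains every top-level gene whose start lies in the half-open circular
#' arc up to the next promoter's tss. The nearest terminator call after the
#' unit's last mRNA/rRNA gene (and before the next tss) is attached. Units
#' are labelled with roman numerals in circle order starting from the unit
#' containing rnl (when present), mirroring the experimentally determined
#' unit maps of entomopathogenic fungal mitogenomes.
#'
#' @param annotation Annotation tibble (with attribute `genome_length`).
#' @param promoters Promoter calls from [find_promoters] (at least one).
#' @param terminators Optional terminator calls from [find_terminators].
#' @return A tibble with one row per unit: `label`, `genes` (list column of
#'   top-level gene names in transcription order), `tss`, `n_genes`,
#'   `terminator_feature`, `terminator_position`, `terminator_distance`,
#'   `length_bp` (tss through the terminator motif end or the last gene end,
#'   whichever is farther).
#' @export
segment_units <- function(annotation, promoters, terminators = NULL) {
  L <- attr(annotation, "genome_length")
  if (is.null(L)) abort("annotation lacks a genome_length attribute")
  if (is.null(promoters) || nrow(promoters) == 0L) {
    abort(paste("no promoters supplied; run find_promoters() first or",
                "provide manual tss anchors"))
  }
  tsss <- sort(unique(promoters$tss %% L))
  k <- length(tsss)
  arc_len <- if (k == 1L) L else (tsss[c(2:k, 1L)] - tsss) %% L
  arc_len[arc_len == 0L] <- L

  genes <- dplyr::filter(annotation, is.na(.data$parent))
  span <- .span_len(genes$start, genes$end, L)
  offs <- outer(genes$start, tsss, function(g, t) (g - t) %% L)
  arc <- apply(offs, 1, which.min)
  off_in_arc <- offs[cbind(seq_len(nrow(genes)), arc)]
  over <- off_in_arc + span > arc_len[arc]
  if (any(over)) {
    warn(paste0("gene(s) wrapping past the next tss kept in the arc of ",
                "their start: ", paste(genes$name[over], collapse = ", ")))
  }

  units <- lapply(seq_len(k), function(i) {
    in_arc <- which(arc == i)
    in_arc <- in_arc[order(off_in_arc[in_arc])]
    gnames <- genes$name[in_arc]
    if (!length(gnames)) return(NULL)
    last_end_off <- max(off_in_arc[in_arc] + span[in_arc])
    # terminator of the last mRNA/rRNA gene, if called before the next tss
    term <- NULL
    coding <- in_arc[genes$kind[in_arc] %in% c("mRNA", "rRNA")]
    if (length(coding) && !is.null(terminators) && nrow(terminators)) {
      last_coding <- genes$name[coding[which.max(off_in_arc[coding])]]
      cand <- dplyr::filter(terminators, .data$feature == last_coding)
      if (nrow(cand)) {
        t_off <- (cand$position[1] - tsss[i]) %% L
        if (t_off < arc_len[i]) term <- cand[1, ]
      }
    }
    end_off <- if (!is.null(term)) {
      max(last_end_off, (term$position - tsss[i]) %% L + nchar(term$matched))
    } else last_end_off
    tibble(
      genes = list(gnames), tss = tsss[i], n_genes = length(gnames),
      terminator_feature = if (is.null(term)) NA_character_ else term$feature,
      terminator_position = if (is.null(term)) NA_integer_ else term$position,
      terminator_distance = if (is.null(term)) NA_integer_ else term$distance_nt,
      length_bp = as.integer(end_off)
    )
  })
  out <- dplyr::bind_rows(units)
  # canonical labelling: start roman numbering at the rnl-bearing unit
  has_rnl <- which(purrr::map_lgl(out$genes, ~ "rnl" %in% .x))
  first <- if (length(has_rnl)) has_rnl[1] else 1L
  ord <- c(first:nrow(out), seq_len(first - 1L))
  out <- out[ord, ]
  out$label <- as.character(utils::as.roman(seq_len(nrow(out))))
  dplyr::select(out, "label", dplyr::everything())
}

#' Mature transcripts under the tRNA punctuation model
#'
#' Cleaves each unit at every tRNA 5' and 3' boundary: every tRNA is excised
#' as its own mature transcript; the remaining fragments between cut points
#' become mRNA/rRNA products (classified by gene content) or gene-less
#' `spacer` fragments when two tRNAs are adjacent. Nested genes (e.g. rps3
#' inside rnl) stay inside their parent's product. A terminator call for the
#' unit's last mRNA/rRNA gene marks the 3' end of the fragment holding it
#' (`signals_used` records `TAAATT`). Product spans tile the unit exactly.
#'
#' @param units Units tibble from [segment_units] (all rows are processed).
#' @param annotation Annotation tibble.
#' @return A tibble with `unit`, `kind` (`mRNA`, `rRNA`, `tRNA` or `spacer`),
#'   `genes` (list column, including nested genes), `start`/`end` (0-based
#'   circular genome span) and `signals_used` (list column).
#' @export
mature_transcripts <- function(units, annotation) {
  L <- attr(annotation, "genome_length")
  if (is.null(L)) abort("annotation lacks a genome_length attribute")
  top <- dplyr::filter(annotation, is.na(.data$parent))
  nested <- dplyr::filter(annotation, !is.na(.data$parent))
  out <- purrr::pmap(units, function(label, genes, tss, length_bp,
                                     terminator_feature, terminator_position,
                                     ...) {
    g <- top[match(genes, top$name), ]
    off <- (g$start - tss) %% L
    end_off <- off + .span_len(g$start, g$end, L)
    is_trna <- g$kind == "tRNA"
    cuts <- sort(unique(c(0, off[is_trna], end_off[is_trna], length_bp)))
    cuts <- cuts[cuts <= length_bp]
    term_off <- if (!is.na(terminator_feature)) {
      (terminator_position - tss) %% L
    } else NA_real_
    segs <- purrr::map2(head(cuts, -1), tail(cuts, -1), function(a, b) {
      if (b <= a) return(NULL)
      inside <- which(off >= a & end_off <= b)
      kind <- if (length(inside) && all(is_trna[inside]) && length(inside) == 1L &&
                  off[inside] == a && end_off[inside] == b) {
        "tRNA"
      } else if (any(g$kind[inside] == "rRNA")) "rRNA"
      else if (any(g$kind[inside] == "mRNA")) "mRNA"
      else "spacer"
      gene_names <- g$name[inside]
      # nested genes ride along inside their parent's product
      if (length(gene_names)) {
        gene_names <- c(gene_names, nested$name[nested$parent %in% gene_names])
      }
      signals <- character()
      if (a == 0) signals <- c(signals, "TSS")
      if (a > 0 && a %in% end_off[is_trna]) signals <- c(signals, "tRNA-3prime")
      if (b %in% off[is_trna]) signals <- c(signals, "tRNA-5prime")
      if (kind == "tRNA") signals <- c("tRNA-5prime", "tRNA-3prime")
      if (!is.na(term_off) && term_off >= a && term_off < b) {
        signals <- c(signals, "TAAATT")
      }
      tibble(unit = label, kind = kind, genes = list(gene_names),
             start = (tss + a) %% L, end = (tss + b) %% L,
             seg_start = a, seg_end = b,
             signals_used = list(signals))
    })
    dplyr::bind_rows(segs)
  })
  dplyr::bind_rows(out)
}

#' 5' UTR length of a transcription unit
#'
#' Circular distance from the unit's tss to the first base of the start
#' codon of its first gene, which must be an mRNA (0 = the tss is the A of
#' the ATG).
#'
#' @param units Units tibble from [segment_units] (one or more rows).
#' @param annotation Annotation tibble.
#' @return A tibble with `label`, `first_gene`, `utr5`.
#' @export
utr5_length <- function(units, annotation) {
  L <- attr(annotation, "genome_length")
  if (is.null(L)) abort("annotation lacks a genome_length attribute")
  first_gene <- purrr::map_chr(units$genes, 1)
  kind <- annotation$kind[match(first_gene, annotation$name)]
  if (any(kind != "mRNA")) {
    bad <- which(kind != "mRNA")[1]
    abort(sprintf("first gene of unit %s is %s (%s), not an mRNA",
                  units$label[bad], first_gene[bad], kind[bad]))
  }
  gstart <- annotation$start[match(first_gene, annotation$name)]
  tibble(label = units$label, first_gene = first_gene,
         utr5 = as.integer((gstart - units$tss) %% L))
}

#' The experimentally determined transcription-unit map
#'
#' Ships the six-unit polycistronic map of the *M. brunneum* ARSEF 3297 and
#' *B. bassiana* mitogenomes (RT-PCR / Northern evidence) as a packaged
#' fixture: ordered gene content per unit plus approximate transcript sizes
#' in kb per species. The unit VI entry stores the ambiguous trnV/trnL tRNA
#' as trnV with an `alias` field.
#'
#' @return A tibble with `label`, `genes` (list column), `nested` (list
#'   column), `alias` (list column), `size_kb_bb`, `size_kb_mb`.
#' @export
reference_unit_map <- function() {
  path <- system.file("extdata", "unit_map_experimental.json",
                      package = "mitotrx", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  dplyr::bind_rows(purrr::map(raw$units, function(u) {
    tibble(label = u$label,
           genes = list(unlist(u$genes)),
           nested = list(unlist(u$nested) %||% character()),
           alias = list(unlist(u$alias) %||% character()),
           size_kb_bb = u$size_kb_bb, size_kb_mb = u$size_kb_mb)
  }))
}

#' Concordance between predicted and reference transcription units
#'
#' Greedy best-matching of predicted against reference units by gene-set
#' Jaccard similarity (top-level genes). `exact_matches` counts pairs with
#' identical ordered gene lists; `gene_level_jaccard` is the Jaccard averaged
#' over best-matched pairs. Invariant to rotation and labelling.
#'
#' @param units Units tibble from [segment_units].
#' @param reference A reference map, e.g. [reference_unit_map()].
#' @return A one-row tibble: `n_predicted`, `n_reference`, `exact_matches`,
#'   `gene_level_jaccard`.
#' @export
compare_to_reference <- function(units, reference) {
  if (nrow(units) == 0L || nrow(reference) == 0L) {
    abort("both unit sets must be non-empty")
  }
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  m <- outer(seq_len(nrow(units)), seq_len(nrow(reference)),
             Vectorize(function(i, j) jac(units$genes[[i]], reference$genes[[j]])))
  exact <- 0L
  jsum <- 0
  npairs <- min(nrow(units), nrow(reference))
  mm <- m
  for (s in seq_len(npairs)) {
    best <- which(mm == max(mm), arr.ind = TRUE)[1, ]
    i <- best[1]; j <- best[2]
    jsum <- jsum + m[i, j]
    if (identical(as.character(units$genes[[i]]),
                  as.character(reference$genes[[j]]))) {
      exact <- exact + 1L
    }
    mm[i, ] <- -1; mm[, j] <- -1
  }
  tibble(n_predicted = nrow(units), n_reference = nrow(reference),
         exact_matches = exact, gene_level_jaccard = jsum / npairs)
}

#' Export transcription units and mature transcripts as GFF3
#'
#' @param units Units tibble from [segment_units].
#' @param mature Optional mature transcripts from [mature_transcripts].
#' @param path Output path.
#' @param seqid Sequence identifier.
#' @export
write_units_gff3 <- function(units, mature = NULL, path, seqid = "genome") {
  rows <- unlist(purrr::pmap(units, function(label, tss, length_bp, ...) {
    sprintf("%s\tmitotrx\ttranscription_unit\t%d\t%d\t.\t+\t.\tID=unit_%s",
            seqid, tss + 1L, tss + length_bp, label)
  }))
  if (!is.null(mature) && nrow(mature)) {
    tss_of <- setNames(units$tss, units$label)
    # unrolled circular coordinates: children share the unit's frame, so a
    # unit crossing the origin keeps end > start (end may exceed the genome
    # length; re-wrap with modulo when mapping back)
    rows <- c(rows, unlist(purrr::pmap(mature, function(unit, kind, genes,
                                                        seg_start, seg_end,
                                                        ...) {
      type <- if (kind == "spacer") "processed_fragment" else kind
      sprintf("%s\tmitotrx\t%s\t%d\t%d\t.\t+\t.\tParent=unit_%s;genes=%s",
              seqid, type, tss_of[[unit]] + seg_start + 1L,
              tss_of[[unit]] + seg_end, unit, paste(genes, collapse = ","))
    })))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Human-readable transcription-unit report
#'
#' Mirrors the layout of the published unit table: one line per unit with its
#' ordered gene content and span.
#'
#' @param units Units tibble from [segment_units].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return The report lines, invisibly when written to a file.
#' @export
unit_report <- function(units, path = NULL) {
  lines <- c(
    sprintf("%-5s %-70s %10s", "Unit", "Gene composition", "Size (kb)"),
    unlist(purrr::pmap(units, function(label, genes, length_bp, ...) {
      sprintf("%-5s %-70s %10.1f", label, paste(genes, collapse = "-"),
              length_bp / 1000)
    }))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
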