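#' Circular mitochondrial genome objects
#'
#' `circular_genome()` wraps a DNA sequence (IUPAC alphabet) together with an
#' identifier and a topology flag. All package coordinates are 0-based,
#' half-open, on the forward strand; on a circular genome every coordinate is
#' taken modulo the genome length, and a feature whose `end` is smaller than
#' its `start` wraps across the origin.
#'
#' @param sequence A single DNA string (upper- or lower-case IUPAC codes).
#' @param id Identifier for the molecule.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`, `sequence`,
#'   `length` and `topology`.
#' @export
circular_genome <- function(sequence, id = "genome",
                            topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("empty sequence")
  if (!.valid_dna(sequence)) {
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), names(IUPAC_SETS))
    abort(paste0("invalid IUPAC nucleotide symbol(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         topology = topology),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read a single-record genome from FASTA or GenBank
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"genbank"`.
#' @param topology Topology to assume when the file metadata does not state
#'   one (FASTA never does; GenBank LOCUS lines usually do).
#' @return A [circular_genome].
#' @export
read_genome <- function(path, format = c("fasta", "genbank"),
                        topology = "circular") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1L) {
      abort(sprintf("expected exactly one FASTA record, found %d", length(set)))
    }
    circular_genome(as.character(set[[1]]), id = names(set)[1],
                    topology = topology)
  } else {
    gb <- .parse_genbank(path)
    circular_genome(gb$sequence, id = gb$id,
                    topology = gb$topology %||% topology)
  }
}

#' Write a genome to FASTA
#'
#' @param genome A [circular_genome].
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet and is an involution:
#' `revcomp(revcomp(s)) == s`.
#'
#' @param x A DNA string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# circular substring, 0-based half-open; start == end gives ""
.circ_substr <- function(sequence, start, end) {
  L <- nchar(sequence)
  start <- start %% L
  end <- end %% L
  if (start == end) return("")
  if (start < end) {
    substr(sequence, start + 1L, end)
  } else {
    paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
  }
}

# span of a 0-based half-open (possibly wrapping) interval
.span_len <- function(start, end, L) {
  ifelse(end >= start, end - start, end + L - start)
}

#' Extract sequence from a (possibly wrapping) genome interval
#'
#' @param genome A [circular_genome].
#' @param start,end 0-based half-open coordinates; `end < start` wraps across
#'   the origin on a circular genome.
#' @return A DNA string.
#' @export
genome_slice <- function(genome, start, end) {
  if (genome$topology == "linear" && end < start) {
    abort("interval wraps the origin on a linear genome")
  }
  .circ_substr(genome$sequence, start, end)
}

#' Rotate a circular genome (and optionally its annotation)
#'
#' The base at position `k` of the input becomes position 0 of the output.
#' Annotation coordinates are shifted accordingly. Used mostly to test
#' rotation invariance of downstream calls.
#'
#' @param genome A [circular_genome] with circular topology.
#' @param k Rotation offset in bp.
#' @param annotation Optional annotation tibble (see [read_annotation]).
#' @return The rotated genome, or a list `(genome, annotation)` when an
#'   annotation is supplied.
#' @export
rotate_genome <- function(genome, k, annotation = NULL) {
  if (genome$topology != "circular") abort("cannot rotate a linear genome")
  L <- genome$length
  k <- k %% L
  g2 <- circular_genome(paste0(substr(genome$sequence, k + 1L, L),
                               substr(genome$sequence, 1L, k)),
                        id = genome$id)
  if (is.null(annotation)) return(g2)
  ann2 <- annotation
  ann2$start <- (annotation$start - k) %% L
  ann2$end <- (annotation$end - k) %% L
  ann2 <- .sort_annotation(ann2, L)
  attr(ann2, "genome_length") <- L
  list(genome = g2, annotation = ann2)
}

#' Collapse an exact terminal repeat
#'
#' Assembled circular contigs sometimes carry the first bases duplicated at
#' the end. If the sequence ends with an exact copy of its prefix, trim the
#' suffix copy (the longest such repeat up to `max_repeat` bp).
#'
#' @param genome A [circular_genome].
#' @param max_repeat Longest repeat length considered.
#' @return The (possibly trimmed) genome.
#' @export
collapse_terminal_repeat <- function(genome, max_repeat = 1000L) {
  s <- genome$sequence
  L <- nchar(s)
  for (p in seq(min(max_repeat, L - 1L), 1L)) {
    if (substr(s, 1L, p) == substr(s, L - p + 1L, L)) {
      return(circular_genome(substr(s, 1L, L - p), id = genome$id,
                             topology = genome$topology))
    }
  }
  genome
}

#' Base composition statistics
#'
#' Percentages are computed over unambiguous A/C/G/T symbols only; ambiguous
#' IUPAC symbols are tallied separately and excluded from both numerator and
#' denominator.
#'
#' @param sequence A DNA string (or a [circular_genome]).
#' @return A one-row tibble with `at_pct`, `gc_pct`, `n_ambiguous` and the
#'   per-symbol counts as a list column `counts`.
#' @export
composition <- function(sequence) {
  if (inherits(sequence, "circular_genome")) sequence <- sequence$sequence
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("composition() needs one non-empty DNA string")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% names(IUPAC_SETS))) abort("invalid nucleotide symbol")
  counts <- table(factor(chars, levels = names(IUPAC_SETS)))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0L) abort("sequence has no unambiguous bases")
  tibble(
    at_pct = 100 * sum(counts[c("A", "T")]) / acgt,
    gc_pct = 100 * sum(counts[c("C", "G")]) / acgt,
    n_ambiguous = length(chars) - acgt,
    counts = list(counts[counts > 0])
  )
}

# round half away from zero, to match printed integer percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Intergenic regions of an annotated circular genome
#'
#' One region per adjacent pair of top-level (non-nested) features around the
#' circle: `n` features give `n` regions. Overlapping neighbours are reported
#' with `length = 0` and `overlap_bp > 0`; abutting neighbours with both 0.
#'
#' @param genome A [circular_genome].
#' @param annotation Annotation tibble (see [read_annotation]).
#' @return A tibble with columns `upstream_gene`, `downstream_gene`, `start`,
#'   `end`, `length`, `overlap_bp`, `sequence`, in circle order.
#' @export
extract_intergenic <- function(genome, annotation) {
  feats <- dplyr::filter(annotation, is.na(.data$parent))
  if (nrow(feats) == 0L) abort("annotation has no top-level features")
  L <- genome$length
  feats <- .sort_annotation(feats, L)
  n <- nrow(feats)
  # unroll: end_u >= start_u always; consecutive starts ascending
  start_u <- feats$start
  end_u <- ifelse(feats$end >= feats$start, feats$end, feats$end + L)
  nxt <- c(2:n, 1L)[seq_len(n)]
  if (n == 1L) nxt <- 1L
  gap_start <- end_u
  gap_end <- start_u[nxt] + ifelse(seq_len(n) == n | n == 1L, L, 0)
  gap <- gap_end - gap_start
  tibble(
    upstream_gene = feats$name,
    downstream_gene = feats$name[nxt],
    start = gap_start %% L,
    end = gap_end %% L,
    length = pmax(gap, 0L),
    overlap_bp = pmax(-gap, 0L),
    sequence = vapply(seq_len(n), function(i) {
      if (gap[i] <= 0) "" else .circ_substr(genome$sequence, gap_start[i], gap_end[i])
    }, "")
  )
}

#' In-silico PCR
#'
#' Finds forward-primer sites on the forward strand and reverse-primer sites
#' on the reverse strand (the reverse primer is given 5'->3' as synthesized),
#' allowing up to `max_mismatch` mismatches, then pairs each forward site with
#' the nearest downstream reverse site on the circle. Amplicon length is
#' measured from the 5' end of the forward primer through the 5' end of the
#' reverse primer, inclusive. Only the shortest product per forward site is
#' reported.
#'
#' @param genome A [circular_genome].
#' @param fwd,rev Primer sequences, 5'->3' (IUPAC codes allowed).
#' @param max_mismatch Maximum mismatches per primer site.
#' @return A tibble with `fwd_start`, `rev_start`, `length`, `sequence`
#'   (possibly zero rows).
#' @export
in_silico_pcr <- function(genome, fwd, rev, max_mismatch = 0L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    abort("primers must be at least 15 nt")
  }
  L <- genome$length
  fwd_sites <- .primer_sites(genome, fwd, max_mismatch)          # 5' ends
  rev_rc <- revcomp(rev)                                          # + strand image
  rev_starts <- .primer_sites(genome, rev_rc, max_mismatch)
  rev5 <- (rev_starts + nchar(rev) - 1L) %% L                     # 5' end of rev
  if (length(fwd_sites) == 0L || length(rev5) == 0L) {
    return(tibble(fwd_start = integer(), rev_start = integer(),
                  length = integer(), sequence = character()))
  }
  rows <- lapply(fwd_sites, function(f) {
    d <- (rev5 - f) %% L
    r <- rev5[which.min(d)]
    len <- min(d) + 1L
    tibble(fwd_start = f, rev_start = r, length = len,
           sequence = .circ_substr(genome$sequence, f, (f + len) %% L))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$fwd_start)
}

# 0-based 5'-end positions of primer matches on the forward strand,
# circular-aware (pattern IUPAC codes are degenerate, subject is concrete)
.primer_sites <- function(genome, primer, max_mismatch) {
  L <- genome$length
  subj <- genome$sequence
  if (genome$topology == "circular" && nchar(primer) > 1L) {
    subj <- paste0(subj, substr(genome$sequence, 1L, nchar(primer) - 1L))
  }
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(subj),
                                max.mismatch = max_mismatch,
                                fixed = "subject")
  pos <- BiocGenerics::start(m) - 1L
  sort(unique(pos[pos < L]))
}
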