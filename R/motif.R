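#' Degenerate IUPAC motifs
#'
#' @param symbols Motif string over the IUPAC nucleotide alphabet
#'   (e.g. `"WTAGWWHWWHD"`; W = A/T, H = A/C/T, D = A/G/T, N = any).
#' @param label Motif label carried into hit tables.
#' @return An object of class `iupac_motif`.
#' @export
iupac_motif <- function(symbols, label = symbols) {
  symbols <- toupper(symbols)
  if (!.valid_dna(symbols)) abort("invalid IUPAC symbol in motif")
  structure(list(symbols = symbols, length = nchar(symbols), label = label),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("<iupac_motif> %s (%d nt)%s\n", x$symbols, x$length,
              if (x$label != x$symbols) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Built-in motif presets
#'
#' Named presets used throughout the pipeline:
#' * `hypocreales` -- `WTAGWWHWWHD`, the order-level degenerate consensus of
#'   the mitochondrial promoter in Hypocreales; the canonical scanning motif.
#' * `promoter_11mer` -- `ATAGTTATTAT`, the literal 11-mer promoter consensus.
#' * `promoter_12mer` -- `TTAGAATATTAT`, the literal 12-mer consensus reported
#'   for *Beauveria*/*Metarhizium* mitogenomes.
#' * `yeast_nonanucleotide` -- `ATATAAGTA`, the *S. cerevisiae* promoter.
#' * `terminator` -- `TAAATT`, the 3'-end processing / termination hexamer.
#'
#' @return A named list of [iupac_motif] objects.
#' @export
motif_presets <- function() {
  list(
    hypocreales = iupac_motif("WTAGWWHWWHD", label = "hypocreales"),
    promoter_11mer = iupac_motif("ATAGTTATTAT", label = "promoter_11mer"),
    promoter_12mer = iupac_motif("TTAGAATATTAT", label = "promoter_12mer"),
    yeast_nonanucleotide = iupac_motif("ATATAAGTA", label = "yeast_nonanucleotide"),
    terminator = iupac_motif("TAAATT", label = "terminator")
  )
}

# logical L x 15 matrix: does motif position i accept region symbol s?
# ambiguous region symbols never match (only concrete A/C/G/T can).
.motif_accept_matrix <- function(symbols) {
  chars <- strsplit(symbols, "")[[1]]
  m <- matrix(FALSE, nrow = length(chars), ncol = length(IUPAC_SETS),
              dimnames = list(NULL, names(IUPAC_SETS)))
  for (i in seq_along(chars)) m[i, IUPAC_SETS[[chars[i]]]] <- TRUE
  m
}

# windows x motif-length index matrix over an integer-coded sequence
.window_mismatches <- function(codes, accept) {
  L <- nrow(accept)
  W <- length(codes) - L + 1L
  if (W < 1L) return(integer(0))
  idx <- outer(seq_len(W) - 1L, seq_len(L), "+")
  ok <- matrix(accept[cbind(rep(seq_len(L), each = W), codes[idx])],
               nrow = W)
  as.integer(L - rowSums(ok))
}

.encode_dna <- function(region) {
  codes <- match(strsplit(toupper(region), "")[[1]], names(IUPAC_SETS))
  if (anyNA(codes)) abort("invalid nucleotide symbol in region")
  codes
}

#' Scan a region with a degenerate IUPAC motif
#'
#' A window matches when at most `max_mismatch` of its bases fall outside the
#' corresponding motif symbol's base set. Positions are 0-based on the region.
#'
#' @param motif An [iupac_motif] (or a plain IUPAC string).
#' @param region DNA string to scan.
#' @param max_mismatch Maximum mismatching positions per window.
#' @param strands `"sense"` (default) or `"both"`. Minus-strand hits are
#'   reported at the 0-based start of the window on the forward coordinates,
#'   with `matched` giving the minus-strand (reverse-complemented) sequence.
#' @return A tibble of hits: `position`, `strand`, `matched`, `mismatches`,
#'   `score` (`NA` for IUPAC scans), `motif_label`, sorted by position then
#'   strand.
#' @export
scan_iupac <- function(motif, region, max_mismatch = 0L,
                       strands = c("sense", "both")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- iupac_motif(motif)
  empty <- tibble(position = integer(), strand = character(),
                  matched = character(), mismatches = integer(),
                  score = double(), motif_label = character())
  n <- nchar(region)
  if (n < motif$length) return(empty)
  accept <- .motif_accept_matrix(motif$symbols)
  one_strand <- function(seqstr, strand_lab) {
    mm <- .window_mismatches(.encode_dna(seqstr), accept)
    pos <- which(mm <= max_mismatch) - 1L
    if (!length(pos)) return(empty)
    tibble(
      position = if (strand_lab == "+") pos else n - pos - motif$length,
      strand = strand_lab,
      matched = substring(seqstr, pos + 1L, pos + motif$length),
      mismatches = mm[pos + 1L],
      score = NA_real_,
      motif_label = motif$label
    )
  }
  hits <- one_strand(region, "+")
  if (strands == "both") {
    hits <- bind_rows(hits, one_strand(revcomp(region), "-"))
  }
  dplyr::arrange(hits, .data$position, .data$strand)
}

#' Build a position weight matrix from aligned signal instances
#'
#' `probs[i, b] = (count_b(i) + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param instances Character vector of equal-length, unambiguous DNA strings
#'   (at least two).
#' @param pseudocount Per-base pseudocount (default 0.25, suited to the small
#'   instance sets promoter alignments provide).
#' @param background Background base frequencies (A, C, G, T).
#' @return An object of class `pwm` with fields `probs` (L x 4), `pseudocount`,
#'   `background`, `n_instances`.
#' @export
build_pwm <- function(instances, pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  inst <- .check_instances(instances)
  n <- nrow(inst)
  counts <- apply(inst, 2, function(col) {
    table(factor(col, levels = c("A", "C", "G", "T")))
  })
  probs <- t((counts + pseudocount) / (n + 4 * pseudocount))
  colnames(probs) <- c("A", "C", "G", "T")
  structure(
    list(probs = probs, pseudocount = pseudocount,
         background = setNames(as.numeric(background), c("A", "C", "G", "T")),
         n_instances = n, length = nrow(probs)),
    class = "pwm"
  )
}

.check_instances <- function(instances) {
  if (length(instances) < 2L) abort("need at least 2 instances")
  instances <- toupper(instances)
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L) abort("instances have ragged lengths")
  mat <- do.call(rbind, strsplit(instances, ""))
  if (!all(mat %in% c("A", "C", "G", "T"))) {
    abort("instances must be unambiguous A/C/G/T strings")
  }
  mat
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d positions, %d instances, pseudocount %.3g\n",
              x$length, x$n_instances, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Scan a region with a PWM
#'
#' Windows are scored as `sum(log2(probs[i, base] / background[base]))` (bits)
#' and reported when the score reaches `threshold_frac` times the maximum
#' attainable score. Windows containing ambiguous bases are disqualified.
#'
#' @param pwm A [build_pwm] object.
#' @param region DNA string to scan.
#' @param threshold_frac Fraction of the maximum attainable score in (0, 1].
#' @return A hit tibble as in [scan_iupac], with `score` filled in.
#' @export
scan_pwm <- function(pwm, region, threshold_frac = 0.8) {
  if (!is.numeric(threshold_frac) || threshold_frac <= 0 || threshold_frac > 1) {
    abort("threshold_frac must be in (0, 1]")
  }
  empty <- tibble(position = integer(), strand = character(),
                  matched = character(), mismatches = integer(),
                  score = double(), motif_label = character())
  L <- pwm$length
  n <- nchar(region)
  if (n < L) return(empty)
  lo <- log2(sweep(pwm$probs, 2, pwm$background[colnames(pwm$probs)], "/"))
  chars <- strsplit(toupper(region), "")[[1]]
  base_idx <- match(chars, c("A", "C", "G", "T"))  # NA for ambiguity codes
  W <- n - L + 1L
  idx <- outer(seq_len(W) - 1L, seq_len(L), "+")
  sc <- matrix(lo[cbind(rep(seq_len(L), each = W), base_idx[idx])], nrow = W)
  scores <- rowSums(sc)                       # NA when window has ambiguity
  max_score <- sum(apply(lo, 1, max))
  pos <- which(!is.na(scores) & scores >= threshold_frac * max_score) - 1L
  if (!length(pos)) return(empty)
  tibble(
    position = pos, strand = "+",
    matched = substring(region, pos + 1L, pos + L),
    mismatches = NA_integer_,
    score = scores[pos + 1L],
    motif_label = "pwm"
  )
}

#' Build a degenerate IUPAC consensus from aligned instances
#'
#' Per position: emit the single base whose frequency reaches `t_major`;
#' otherwise emit the smallest IUPAC code covering every base whose frequency
#' exceeds `t_cover`.
#'
#' @inheritParams build_pwm
#' @param t_major Majority threshold in \[0.5, 1\].
#' @param t_cover Coverage threshold in \[0, t_major).
#' @param label Label for the resulting motif.
#' @return An [iupac_motif].
#' @export
build_consensus <- function(instances, t_major = 0.75, t_cover = 0,
                            label = "consensus") {
  if (t_major < 0.5 || t_major > 1) abort("t_major must be in [0.5, 1]")
  if (t_cover < 0 || t_cover >= t_major) abort("t_cover must be in [0, t_major)")
  inst <- .check_instances(instances)
  n <- nrow(inst)
  syms <- apply(inst, 2, function(col) {
    freq <- table(factor(col, levels = c("A", "C", "G", "T"))) / n
    if (max(freq) >= t_major) {
      names(freq)[which.max(freq)]
    } else {
      present <- sort(names(freq)[freq > t_cover])
      IUPAC_FROM_SET[[paste(present, collapse = "")]]
    }
  })
  iupac_motif(paste(syms, collapse = ""), label = label)
}

#' Tidy a PWM into a long tibble
#'
#' @param x A [build_pwm] object.
#' @param ... Unused.
#' @return A tibble with `position` (1-based within the motif), `base`,
#'   `prob` and `bits` (log2 odds vs background).
#' @export
tidy.pwm <- function(x, ...) {
  lo <- log2(sweep(x$probs, 2, x$background[colnames(x$probs)], "/"))
  tibble(
    position = rep(seq_len(x$length), times = 4L),
    base = rep(colnames(x$probs), each = x$length),
    prob = as.vector(x$probs),
    bits = as.vector(lo)
  )
}

#' Plot a PWM as a per-position probability profile
#'
#' @param object A [build_pwm] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$prob,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "motif position", y = "base probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a motif or PWM to JSON
#'
#' @param x An [iupac_motif] or [build_pwm] object.
#' @param path Output path.
#' @export
write_motif_json <- function(x, path) {
  obj <- if (inherits(x, "pwm")) {
    list(type = "pwm", probs = unclass(x$probs), background = x$background,
         pseudocount = x$pseudocount, n_instances = x$n_instances)
  } else {
    list(type = "iupac", symbols = x$symbols, label = x$label)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a PWM as a minimal MEME-style text block
#'
#' @param pwm A [build_pwm] object.
#' @param path Output path.
#' @param name Motif name in the block.
#' @export
write_pwm_meme <- function(pwm, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       pwm$length, pwm$n_instances)), con)
  write.table(format(pwm$probs, digits = 6), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
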