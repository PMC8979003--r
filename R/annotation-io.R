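#' Gene annotations as tibbles
#'
#' An annotation is a tibble with one row per gene feature and columns
#' `name` (unique), `kind` (`"mRNA"`, `"rRNA"` or `"tRNA"`), `start`/`end`
#' (0-based half-open, forward strand; `end < start` wraps the origin),
#' `strand` (`"+"`/`"-"`) and `parent` (`NA` for top-level features; set for
#' genes nested inside another gene's span, e.g. rps3 inside rnl). The genome
#' length is carried as attribute `genome_length`.
#'
#' @param features Tibble (or data.frame) with the columns above (`parent`
#'   optional).
#' @param genome_length Genome length in bp.
#' @return A validated, circularly sorted annotation tibble.
#' @export
annotation <- function(features, genome_length) {
  f <- as_tibble(features)
  if (!all(c("name", "kind", "start", "end", "strand") %in% names(f))) {
    abort("annotation needs columns name, kind, start, end, strand")
  }
  if (!"parent" %in% names(f)) f$parent <- NA_character_
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  if (anyDuplicated(f$name)) {
    abort(paste0("duplicated feature names: ",
                 paste(unique(f$name[duplicated(f$name)]), collapse = ", ")))
  }
  bad <- setdiff(unique(f$kind), c("mRNA", "rRNA", "tRNA"))
  if (length(bad)) abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
  if (any(f$start < 0 | f$start >= genome_length)) {
    abort("feature start outside [0, genome_length)")
  }
  f <- .assign_parents(f, genome_length)
  f <- .sort_annotation(f, genome_length)
  attr(f, "genome_length") <- genome_length
  f
}

# sort by circular order of start (top-level and nested alike)
.sort_annotation <- function(f, L) {
  dplyr::arrange(f, .data$start, .data$end)
}

# a feature wholly inside another feature's span becomes its child;
# the smallest containing feature wins
.assign_parents <- function(f, L) {
  n <- nrow(f)
  span <- .span_len(f$start, f$end, L)
  parent <- f$parent
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) next
    container <- NA_integer_
    for (j in seq_len(n)) {
      if (i == j) next
      if (span[j] <= span[i]) next
      # offset of i's span inside j's span on the unrolled circle
      off <- (f$start[i] - f$start[j]) %% L
      if (off + span[i] <= span[j]) {
        if (is.na(container) || span[j] < span[container]) container <- j
      }
    }
    if (!is.na(container)) parent[i] <- f$name[container]
  }
  f$parent <- parent
  f
}

#' Read a gene annotation from GFF3 or a GenBank flat file
#'
#' File coordinates are 1-based inclusive in both formats and are converted
#' to the package's internal 0-based half-open convention. Feature kinds are
#' mapped as CDS/mRNA -> mRNA, rRNA -> rRNA, tRNA -> tRNA; any other feature
#' type is ignored with a warning. Genes contained in another gene's span are
#' marked nested via `parent`.
#'
#' @param path Path to the file.
#' @param format `"gff3"` or `"genbank"`.
#' @param genome_length Genome length in bp (required for GFF3; taken from
#'   the LOCUS line for GenBank when omitted).
#' @return An annotation tibble (see [annotation]).
#' @export
read_annotation <- function(path, format = c("gff3", "genbank"),
                            genome_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "gff3") {
    if (is.null(genome_length)) abort("genome_length is required for GFF3 input")
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    kind <- dplyr::case_when(
      type %in% c("CDS", "mRNA") ~ "mRNA",
      type == "rRNA" ~ "rRNA",
      type == "tRNA" ~ "tRNA",
      TRUE ~ NA_character_
    )
    if (anyNA(kind)) {
      warn(paste0("ignoring feature type(s): ",
                  paste(unique(type[is.na(kind)]), collapse = ", ")))
    }
    keep <- !is.na(kind)
    nm <- gr$Name %||% gr$ID
    if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
    f <- tibble(
      name = as.character(nm)[keep],
      kind = kind[keep],
      start = BiocGenerics::start(gr)[keep] - 1L,
      end = BiocGenerics::end(gr)[keep],
      strand = ifelse(as.character(BiocGenerics::strand(gr))[keep] == "-", "-", "+")
    )
    if (any(f$end > genome_length)) {
      abort("feature exceeds the stated genome length")
    }
    annotation(f, genome_length)
  } else {
    gb <- .parse_genbank(path)
    if (is.null(genome_length)) genome_length <- nchar(gb$sequence) %||% gb$length
    annotation(gb$features, genome_length)
  }
}

# Minimal GenBank flat-file parser: LOCUS line, FEATURES table (simple and
# complement() locations; join()/order() collapsed to their overall range),
# ORIGIN sequence block. Enough for the mitogenome records this package uses.
.parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) abort("not a GenBank file: no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  topology <- if (any(grepl("circular", locus[1]))) "circular"
              else if (any(grepl("linear", locus[1]))) "linear" else NULL

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  feats <- list()
  ignored <- character()
  if (length(feat_i)) {
    end_i <- if (length(orig_i)) orig_i[1] - 1L else length(lines)
    block <- lines[(feat_i[1] + 1L):end_i]
    key <- NA; loc <- NA; quals <- character()
    flush <- function() {
      if (is.na(key)) return()
      kind <- switch(key, CDS = "mRNA", mRNA = "mRNA", rRNA = "rRNA",
                     tRNA = "tRNA", NA_character_)
      if (is.na(kind)) {
        if (key != "source") ignored[[length(ignored) + 1L]] <<- key
        return()
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      nm <- sub('.*="?([^"]*)"?.*', "\\1",
                grep("/(gene|label|product|locus_tag)=", quals, value = TRUE)[1])
      if (is.na(nm) || !nzchar(nm)) nm <- paste0(key, length(feats) + 1L)
      feats[[length(feats) + 1L]] <<- tibble(
        name = nm,
        kind = kind, start = min(nums) - 1L, end = max(nums), strand = strand
      )
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        flush()
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        quals <- character()
      } else if (grepl("^ +/", ln)) {
        quals <- c(quals, trimws(ln))
      } else if (grepl("^ +\\S", ln) && !length(quals)) {
        loc <- paste0(loc, trimws(ln))  # wrapped location
      }
    }
    flush()
    if (length(ignored)) {
      warn(paste0("ignoring GenBank feature key(s): ",
                  paste(unique(unlist(ignored)), collapse = ", ")))
    }
  }
  sequence <- NULL
  if (length(orig_i)) {
    seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  list(id = id, length = len, topology = topology, sequence = sequence,
       features = if (length(feats)) dplyr::bind_rows(feats) else
         tibble(name = character(), kind = character(), start = integer(),
                end = integer(), strand = character()))
}

#' Write an annotation (or signal calls) as GFF3
#'
#' Coordinates are exported 1-based inclusive. Features wrapping the origin
#' cannot be represented in GFF3 and raise an error.
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @param seqid Sequence identifier for column 1.
#' @export
write_annotation_gff3 <- function(annotation, path, seqid = "genome") {
  if (any(annotation$end < annotation$start)) {
    abort("GFF3 cannot represent features wrapping the origin")
  }
  attrs <- paste0("ID=", annotation$name, ";Name=", annotation$name,
                  ifelse(is.na(annotation$parent), "",
                         paste0(";Parent=", annotation$parent)))
  df <- data.frame(seqid, "mitotrx", annotation$kind,
                   annotation$start + 1L, annotation$end, ".",
                   annotation$strand, ".", attrs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
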