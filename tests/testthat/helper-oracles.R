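# Independent brute-force oracles. These re-derive expected results with
# plain double loops and their own IUPAC lookup so they share no code with
# the implementation they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# all 0-based window starts where the degenerate motif matches with at most
# max_mm mismatching positions
oracle_iupac_positions <- function(motif, region, max_mm = 0) {
  m <- strsplit(motif, "")[[1]]
  r <- strsplit(region, "")[[1]]
  hits <- integer(0)
  if (length(r) < length(m)) return(hits)
  for (s in 0:(length(r) - length(m))) {
    mm <- 0
    for (k in seq_along(m)) {
      if (!(r[s + k] %in% ORACLE_IUPAC[[m[k]]])) mm <- mm + 1
    }
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

# 0-based window starts whose log2-odds PWM score reaches frac of the
# maximum attainable score; windows with ambiguity codes are skipped
oracle_pwm_positions <- function(probs, background, region, frac) {
  r <- strsplit(region, "")[[1]]
  L <- nrow(probs)
  maxsc <- 0
  for (i in seq_len(L)) {
    maxsc <- maxsc + max(log2(probs[i, ] / background))
  }
  hits <- integer(0)
  if (length(r) < L) return(hits)
  for (s in 0:(length(r) - L)) {
    sc <- 0
    ok <- TRUE
    for (i in seq_len(L)) {
      b <- r[s + i]
      if (!b %in% c("A", "C", "G", "T")) { ok <- FALSE; break }
      sc <- sc + log2(probs[i, b] / background[b])
    }
    if (ok && sc >= frac * maxsc) hits <- c(hits, s)
  }
  hits
}

# exact substring occurrences (0-based) on a circular sequence
oracle_circular_find <- function(pattern, sequence) {
  L <- nchar(sequence)
  doubled <- paste0(sequence, sequence)
  hits <- integer(0)
  for (s in 0:(L - 1)) {
    if (substr(doubled, s + 1, s + nchar(pattern)) == pattern) {
      hits <- c(hits, s)
    }
  }
  hits
}

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# small hand-laid circular genome: two genes on a 100 bp circle
toy_genome_pair <- function(seed = 1) {
  set.seed(seed)
  g <- circular_genome(random_dna(100), id = "toy")
  ann <- annotation(
    tibble::tibble(name = c("geneA", "geneB"), kind = c("mRNA", "tRNA"),
                   start = c(10L, 50L), end = c(30L, 70L),
                   strand = "+"),
    genome_length = 100L)
  list(genome = g, annotation = ann)
}
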