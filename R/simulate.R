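#' Simulate a circular mitogenome with planted transcription signals
#'
#' Generates an AT-rich circular genome emulating the structure of
#' entomopathogenic-fungal mitogenomes: 14 protein genes, rnl/rns rRNAs (with
#' rps3 nested inside rnl), 25 tRNA genes in clusters, variable intergenic
#' gaps, promoter instances planted in the intergenic region upstream of each
#' transcription unit's first gene, and 5'-TAAATT-3' terminators planted
#' 1-218 nt downstream of every mRNA/rRNA coding end. The default gene order
#' and unit partition reproduce the experimentally determined six-unit map,
#' so the full pipeline can be validated against a known truth record.
#'
#' By default the background is rejection-scrubbed so that no unplanted
#' window matches the promoter consensus or the terminator hexamer on the
#' sense strand (decoy-free mode); `decoy_rate` re-enables a fraction of the
#' chance matches for robustness experiments.
#'
#' @param genome_length Total length in bp (default 25000).
#' @param at_fraction Background A+T fraction (default 0.72).
#' @param n_mrna,n_rrna,n_trna Gene counts (defaults 14 / 2 / 25).
#' @param trna_cluster_sizes Optional integer vector of tRNA cluster sizes
#'   used when the gene counts deviate from the defaults.
#' @param n_promoter_regions Number of transcription units / planted
#'   promoters (default 6).
#' @param promoter_source `"consensus-literal"` (plant the literal 11-mer
#'   `ATAGTTATTAT`) or `"pwm-sample"` (draw each base uniformly from the
#'   degenerate consensus `WTAGWWHWWHD`).
#' @param terminator_gap_range Range the terminator gap is drawn from
#'   (default `c(1, 218)`).
#' @param utr5_range Range the 5' UTR of unit-first genes is drawn from
#'   (default `c(10, 100)`).
#' @param intergenic_length_range Range intergenic gaps are drawn from before
#'   rescaling to fit the circle exactly (default `c(30, 500)`).
#' @param nested_gene Plant rps3 inside rnl (default `TRUE`).
#' @param decoy_rate Fraction of chance motif matches left unscrubbed
#'   (default 0).
#' @param seed Integer seed; equal seeds give byte-identical output.
#' @return A list of class `mt_simulation`: `genome` ([circular_genome]),
#'   `annotation` (tibble) and `truth` (list with `promoters`,
#'   `terminators`, `unit_partition`, `utr5`, `config`).
#' @export
simulate_genome <- function(genome_length = 25000L,
                            at_fraction = 0.72,
                            n_mrna = 14L, n_rrna = 2L, n_trna = 25L,
                            trna_cluster_sizes = NULL,
                            n_promoter_regions = 6L,
                            promoter_source = c("consensus-literal",
                                                "pwm-sample"),
                            terminator_gap_range = c(1L, 218L),
                            utr5_range = c(10L, 100L),
                            intergenic_length_range = c(30L, 500L),
                            nested_gene = TRUE,
                            decoy_rate = 0,
                            seed = NULL) {
  promoter_source <- match.arg(promoter_source)
  if (!is.null(seed)) set.seed(seed)

  roster <- .gene_roster(n_mrna, n_rrna, n_trna, trna_cluster_sizes,
                         nested_gene)
  n_genes <- nrow(roster)
  if (n_promoter_regions < 1L || n_promoter_regions > n_genes) {
    abort("n_promoter_regions must be between 1 and the gene count")
  }
  unit_of <- .unit_partition(roster, n_promoter_regions)

  # sample() treats a length-1 numeric as 1:x; always index explicitly
  pick <- function(v, n = 1L) v[sample.int(length(v), n, replace = TRUE)]

  bg <- function(n) {
    paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
                 prob = c(at_fraction / 2, at_fraction / 2,
                          (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
          collapse = "")
  }

  # gene lengths and sequences
  glen <- integer(n_genes)
  gseq <- character(n_genes)
  for (i in seq_len(n_genes)) {
    if (roster$kind[i] == "tRNA") {
      glen[i] <- 72L
      gseq[i] <- bg(72L)
    } else if (roster$kind[i] == "rRNA") {
      glen[i] <- if (roster$name[i] == "rnl") 2600L else 1400L
      gseq[i] <- bg(glen[i])
    } else {
      glen[i] <- 3L * pick(100:400)
      gseq[i] <- paste0("ATG", bg(glen[i] - 6L), "TAA")
    }
  }

  # 5' UTRs for unit-first genes (promoter offset for non-mRNA first genes)
  first_of_unit <- !duplicated(unit_of)
  utr5 <- integer(n_genes)
  utr5[first_of_unit] <- pick(utr5_range[1]:utr5_range[2],
                              sum(first_of_unit))

  prom_len <- 11L
  # gap i follows gene i; the promoter of the unit starting at gene i+1 (or
  # gene 1 for the final gap) sits at the gap's 3' end; the terminator of
  # gene i (mRNA/rRNA) sits near its 5' end
  nxt <- c(2:n_genes, 1L)
  needs_term <- roster$kind %in% c("mRNA", "rRNA")
  prom_after <- first_of_unit[nxt]
  prom_space <- ifelse(prom_after, utr5[nxt] + prom_len + 2L, 0L)
  term_space <- ifelse(needs_term, terminator_gap_range[1] + 8L, 0L)
  required <- pmax(2L, term_space + prom_space)

  drawn <- pick(intergenic_length_range[1]:intergenic_length_range[2],
                n_genes)
  desired <- pmax(drawn, required)
  target <- genome_length - sum(glen)
  if (target < sum(required)) {
    abort(sprintf(
      "genome_length %d too small: genes + minimal gaps need %d bp (deficit %d)",
      genome_length, sum(glen) + sum(required), sum(required) - target))
  }
  slack <- desired - required
  f <- if (sum(slack) > 0) (target - sum(required)) / sum(slack) else 0
  gaps <- required + floor(f * slack)
  rem <- target - sum(gaps)
  if (rem > 0) {
    add <- rep(rem %/% n_genes, n_genes)
    add[seq_len(rem %% n_genes)] <- add[seq_len(rem %% n_genes)] + 1L
    gaps <- gaps + add
  }
  stopifnot(sum(gaps) == target, all(gaps >= required))

  # assemble the circle: gene1 starts at 0
  gstart <- cumsum(c(0L, glen + gaps))[seq_len(n_genes)]
  gapseq <- vapply(gaps, bg, "")

  # plant terminators
  term_gap <- rep(NA_integer_, n_genes)
  for (i in which(needs_term)) {
    avail <- gaps[i] - prom_space[i] - 6L - 1L
    g <- pick(terminator_gap_range[1]:min(terminator_gap_range[2], avail))
    term_gap[i] <- g
    substr(gapseq[i], g + 1L, g + 6L) <- "TAAATT"
  }

  # plant promoters at the gap 3' ends
  prom_instance <- rep(NA_character_, n_genes)  # indexed by the gap's gene i
  for (i in which(prom_after)) {
    inst <- if (promoter_source == "consensus-literal") {
      "ATAGTTATTAT"
    } else {
      repeat {
        cand <- paste(vapply(strsplit("WTAGWWHWWHD", "")[[1]],
                             function(s) sample(IUPAC_SETS[[s]], 1L), ""),
                      collapse = "")
        if (!grepl("TAAATT", cand)) break
      }
      cand
    }
    off <- gaps[i] - utr5[nxt[i]] - prom_len
    substr(gapseq[i], off + 1L, off + prom_len) <- inst
    prom_instance[i] <- inst
  }

  seqstr <- paste(as.vector(rbind(gseq, gapseq)), collapse = "")
  stopifnot(nchar(seqstr) == genome_length)

  # annotation (+ nested rps3 inside rnl, with its own start/stop codons)
  feats <- tibble(name = roster$name, kind = roster$kind,
                  start = gstart, end = gstart + glen, strand = "+",
                  parent = NA_character_)
  if (nested_gene && "rnl" %in% roster$name) {
    i <- which(roster$name == "rnl")
    rps3_start <- gstart[i] + 600L
    rps3_len <- 453L
    substr(seqstr, rps3_start + 1L, rps3_start + 3L) <- "ATG"
    substr(seqstr, rps3_start + rps3_len - 2L, rps3_start + rps3_len) <- "TAA"
    feats <- dplyr::bind_rows(feats, tibble(
      name = "rps3", kind = "mRNA", start = rps3_start,
      end = rps3_start + rps3_len, strand = "+", parent = "rnl"))
  }

  # protected spans (0-based positions) that decoy scrubbing must not touch
  protected <- c(
    unlist(lapply(which(needs_term), function(i) {
      p <- gstart[i] + glen[i] + term_gap[i]
      p:(p + 5L)
    })),
    unlist(lapply(which(prom_after), function(i) {
      p <- gstart[i] + glen[i] + gaps[i] - utr5[nxt[i]] - prom_len
      p:(p + prom_len - 1L)
    })),
    unlist(lapply(which(roster$kind == "mRNA"), function(i) {
      c(gstart[i]:(gstart[i] + 2L), (gstart[i] + glen[i] - 3L):(gstart[i] + glen[i] - 1L))
    }))
  )
  planted_prom_pos <- vapply(which(prom_after), function(i) {
    as.integer(gstart[i] + glen[i] + gaps[i] - utr5[nxt[i]] - prom_len)
  }, integer(1))
  planted_term_pos <- vapply(which(needs_term), function(i) {
    as.integer(gstart[i] + glen[i] + term_gap[i])
  }, integer(1))

  seqstr <- .scrub_decoys(seqstr, protected,
                          keep = list(consensus = planted_prom_pos,
                                      terminator = planted_term_pos),
                          decoy_rate = decoy_rate)

  genome <- circular_genome(seqstr, id = sprintf("sim_mt_%s",
                                                 seed %||% "noseed"))
  ann <- annotation(feats, genome_length)

  unit_labels <- paste0("U", unit_of)
  truth <- list(
    promoters = tibble(
      unit = paste0("U", unit_of[nxt[which(prom_after)]]),
      position = planted_prom_pos,
      tss = planted_prom_pos + prom_len,
      downstream_gene = roster$name[nxt[which(prom_after)]],
      instance = prom_instance[which(prom_after)]
    ),
    terminators = tibble(
      feature = roster$name[which(needs_term)],
      gap = term_gap[which(needs_term)],
      position = planted_term_pos
    ),
    unit_partition = tibble(
      unit = paste0("U", seq_len(n_promoter_regions)),
      genes = unname(split(roster$name, unit_of))
    ),
    utr5 = {
      fi <- which(first_of_unit & roster$kind == "mRNA")
      tibble(unit = unit_labels[fi], first_gene = roster$name[fi],
             utr5 = utr5[fi])
    },
    config = list(genome_length = genome_length, at_fraction = at_fraction,
                  n_mrna = n_mrna, n_rrna = n_rrna, n_trna = n_trna,
                  n_promoter_regions = n_promoter_regions,
                  promoter_source = promoter_source,
                  terminator_gap_range = terminator_gap_range,
                  utr5_range = utr5_range,
                  intergenic_length_range = intergenic_length_range,
                  nested_gene = nested_gene, decoy_rate = decoy_rate,
                  seed = seed)
  )
  structure(list(genome = genome, annotation = ann, truth = truth),
            class = "mt_simulation")
}

#' @export
print.mt_simulation <- function(x, ...) {
  cat(sprintf("<mt_simulation> %d bp, %d genes, %d planted promoters\n",
              x$genome$length, nrow(x$annotation), nrow(x$truth$promoters)))
  invisible(x)
}

# canonical mitogenome gene order (circle order, all forward strand); falls
# back to a generic roster when counts deviate from the canonical 14/2/25
.gene_roster <- function(n_mrna, n_rrna, n_trna, trna_cluster_sizes,
                         nested_gene) {
  canonical <- list(
    c("rnl"),
    c("trnT", "trnE", "trnM1", "trnM2", "trnL1", "trnA", "trnF", "trnK",
      "trnL2", "trnQ", "trnH", "trnM3", "nad2", "nad3", "atp9"),
    c("cox2", "trnR1", "nad4L", "nad5", "cob", "trnC"),
    c("cox1", "trnR2"),
    c("nad1", "nad4", "atp8", "atp6"),
    c("rns", "trnY", "trnD", "trnS", "trnN", "cox3", "trnG", "nad6",
      "trnV", "trnI", "trnS2", "trnW", "trnP")
  )
  kind_of <- function(nm) {
    ifelse(grepl("^trn", nm), "tRNA",
           ifelse(nm %in% c("rnl", "rns"), "rRNA", "mRNA"))
  }
  if (n_mrna == 14L && n_rrna == 2L && n_trna == 25L) {
    nm <- unlist(canonical)
    return(tibble(name = nm, kind = kind_of(nm),
                  canonical_unit = rep(seq_along(canonical),
                                       lengths(canonical))))
  }
  rr <- c("rnl", "rns", paste0("rrn", seq_len(max(0, n_rrna - 2L)) + 2L))[seq_len(n_rrna)]
  mm <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "cob",
          "cox1", "cox2", "cox3", "atp6", "atp8", "atp9")
  mm <- c(mm, paste0("orf", seq_len(max(0, n_mrna - length(mm)))))[seq_len(n_mrna)]
  tt <- paste0("trnX", seq_len(n_trna))
  sizes <- trna_cluster_sizes %||%
    {s <- n_trna %/% 2; c(s, n_trna - s)}
  if (sum(sizes) != n_trna) abort("trna_cluster_sizes must sum to n_trna")
  clusters <- split(tt, rep(seq_along(sizes), sizes))
  # interleave: rRNA, cluster, half the mRNAs, rRNA, cluster, ...
  blocks <- list()
  m_split <- split(mm, cut(seq_along(mm), length(sizes), labels = FALSE))
  for (i in seq_along(sizes)) {
    blocks <- c(blocks,
                if (i <= length(rr)) list(rr[i]) else NULL,
                list(clusters[[i]]), list(m_split[[i]]))
  }
  if (length(rr) > length(sizes)) blocks <- c(blocks, list(rr[-seq_along(sizes)]))
  nm <- unlist(blocks)
  tibble(name = nm, kind = kind_of(nm), canonical_unit = NA_integer_)
}

# contiguous unit membership for each roster gene
.unit_partition <- function(roster, n_units) {
  if (!anyNA(roster$canonical_unit) && n_units == max(roster$canonical_unit)) {
    return(roster$canonical_unit)
  }
  n <- nrow(roster)
  cuts <- floor(seq(1, n + 1, length.out = n_units + 1))
  rep(seq_len(n_units), diff(cuts))
}

# iteratively mutate unplanted sense-strand matches of the promoter
# consensus and the terminator hexamer; planted positions and codon spans
# stay untouched
.scrub_decoys <- function(seqstr, protected, keep, decoy_rate = 0,
                          max_iter = 30L) {
  L <- nchar(seqstr)
  protected <- unique(protected %% L)
  accept_cons <- .motif_accept_matrix("WTAGWWHWWHD")
  accept_term <- .motif_accept_matrix("TAAATT")
  tolerated <- integer(0)
  for (iter in seq_len(max_iter)) {
    doubled <- paste0(seqstr, substr(seqstr, 1L, 11L))
    codes <- .encode_dna(doubled)
    decoys <- list()
    for (spec in list(list(acc = accept_cons, keep = keep$consensus),
                      list(acc = accept_term, keep = keep$terminator))) {
      mm <- .window_mismatches(codes, spec$acc)
      pos <- which(mm == 0L) - 1L
      pos <- pos[pos < L]
      pos <- setdiff(pos, c(spec$keep, tolerated))
      if (length(pos)) {
        decoys <- c(decoys, lapply(pos, function(p) {
          list(pos = p, len = nrow(spec$acc), acc = spec$acc)
        }))
      }
    }
    if (!length(decoys)) return(seqstr)
    chars <- strsplit(seqstr, "")[[1]]
    for (d in decoys) {
      if (decoy_rate > 0 && runif(1) < decoy_rate) {
        tolerated <- c(tolerated, d$pos)
        next
      }
      offs <- (d$pos + seq_len(d$len) - 1L) %% L
      mutable <- which(!(offs %in% protected))
      if (!length(mutable)) next  # fully protected; cannot occur by design
      k <- mutable[ceiling(length(mutable) / 2)]
      for (b in c("C", "G", "A")) {
        if (!d$acc[k, b]) { chars[offs[k] + 1L] <- b; break }
      }
    }
    seqstr <- paste(chars, collapse = "")
  }
  abort("decoy scrubbing did not converge")
}

#' Simulate a pair of protein alignments for mirror-tree testing
#'
#' Draws a random tree (branch lengths uniform on `(0, tree_depth)`
#' substitutions/site), then evolves two proteins by a single-rate 20-state
#' uniform-exchange (Poisson) substitution process: in `"shared-tree"` mode
#' both proteins evolve on the same tree (a co-evolving pair); in
#' `"independent"` mode protein B gets its own tree.
#'
#' @param n_taxa Number of taxa (at least 4).
#' @param tree_depth Branch-length scale in substitutions/site (default 0.3;
#'   0 gives identical sequences and degenerate all-zero distances).
#' @param mode `"shared-tree"` or `"independent"`.
#' @param n_sites Alignment length (default 300).
#' @param seed Integer seed.
#' @return A list: `aln_a`, `aln_b` (alignment tibbles), `tree` (the tree of
#'   protein A), `tree_b` (protein B's tree; equals `tree` in shared mode).
#' @export
simulate_coevolving_pair <- function(n_taxa, tree_depth = 0.3,
                                     mode = c("shared-tree", "independent"),
                                     n_sites = 300L, seed = NULL) {
  mode <- match.arg(mode)
  if (n_taxa < 4L) abort("n_taxa must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  draw_tree <- function() {
    tr <- ape::rtree(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- runif(nrow(tr$edge), 0, tree_depth)
    tr
  }
  evolve <- function(tr) {
    if (tree_depth == 0 || sum(tr$edge.length) == 0) {
      root <- paste(sample(Biostrings::AA_STANDARD, n_sites, replace = TRUE),
                    collapse = "")
      return(protein_alignment(tr$tip.label, rep(root, n_taxa)))
    }
    sim <- phangorn::simSeq(tr, l = n_sites, type = "AA")
    m <- as.character(sim)
    protein_alignment(rownames(m), toupper(apply(m, 1, paste, collapse = "")))
  }
  tree_a <- draw_tree()
  aln_a <- evolve(tree_a)
  tree_b <- if (mode == "shared-tree") tree_a else draw_tree()
  aln_b <- evolve(tree_b)
  list(aln_a = aln_a, aln_b = aln_b, tree = tree_a, tree_b = tree_b)
}
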