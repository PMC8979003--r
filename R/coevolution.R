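#' Protein alignments as tibbles
#'
#' An alignment is a tibble with columns `taxon` (unique identifiers) and
#' `seq` (equal-length aligned amino-acid strings, gap symbol `-`).
#'
#' @param taxa Character vector of taxon identifiers.
#' @param seqs Character vector of aligned sequences (same length as `taxa`).
#' @return A validated alignment tibble.
#' @export
protein_alignment <- function(taxa, seqs) {
  if (length(taxa) != length(seqs)) abort("taxa and seqs differ in length")
  if (anyDuplicated(taxa)) abort("duplicated taxon identifiers")
  if (length(unique(nchar(seqs))) > 1L) abort("aligned rows have ragged lengths")
  tibble(taxon = as.character(taxa), seq = toupper(seqs))
}

#' Read an aligned FASTA of protein sequences
#'
#' @param path Path to the aligned FASTA file.
#' @return An alignment tibble (see [protein_alignment]).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  protein_alignment(names(set), as.character(set))
}

#' Pairwise evolutionary distances from an alignment
#'
#' Gaps are handled by pairwise deletion: for each pair only columns where
#' both rows have a non-gap residue are compared. `p` is the mismatch
#' fraction over those columns; the Poisson-corrected distance is
#' `-ln(1 - p)`.
#'
#' @param alignment An alignment tibble (see [protein_alignment]).
#' @param model `"p-distance"` or `"poisson"`.
#' @return A symmetric distance matrix (class `matrix`) with taxa as
#'   dimnames, zero diagonal.
#' @export
pairwise_distances <- function(alignment, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  n <- nrow(alignment)
  if (n < 2L) abort("need at least 2 taxa")
  chars <- do.call(rbind, strsplit(alignment$seq, ""))
  notgap <- chars != "-"
  d <- matrix(0, n, n, dimnames = list(alignment$taxon, alignment$taxon))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- notgap[i, ] & notgap[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        abort(sprintf("no comparable columns for pair %s / %s",
                      alignment$taxon[i], alignment$taxon[j]))
      }
      p <- sum(chars[i, comp] != chars[j, comp]) / nc
      if (model == "poisson") {
        if (p >= 1) {
          abort(sprintf("p = 1 for pair %s / %s: Poisson distance undefined",
                        alignment$taxon[i], alignment$taxon[j]))
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via `ape::nj`); negative branch
#' lengths are clamped to zero with the total deficit reported. Exact on
#' additive matrices: the tree's cophenetic distances reproduce the input.
#'
#' @param dm A symmetric distance matrix with taxa as dimnames (at least 4).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 4L) abort("neighbor joining needs at least 4 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    inform(sprintf("clamped %d negative branch length(s), total deficit %.3g",
                   sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @param digits Branch-length precision (default 6 decimal places).
#' @export
write_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Mirror-tree co-evolution score
#'
#' Restricts both distance matrices to their shared taxa (canonical
#' alphabetical order) and computes the Pearson correlation of the
#' upper-triangle entries. Strong positive correlation between the distance
#' matrices of two protein families (here: the mitochondrial RNA polymerase
#' Rpo41 and its transcription factor Mtf1) indicates co-evolution.
#'
#' @param dmA,dmB Symmetric distance matrices with taxon dimnames sharing at
#'   least 4 identifiers.
#' @return An object of class `mirror_tree_score` with fields `r`, `n_pairs`,
#'   `shared_taxa` and the paired upper-triangle distances. Use [glance()]
#'   for a one-row summary, [tidy()] for the per-pair table.
#' @export
mirror_tree_score <- function(dmA, dmB) {
  shared <- sort(intersect(rownames(dmA), rownames(dmB)))
  if (length(shared) < 4L) abort("fewer than 4 shared taxa")
  a <- as.matrix(dmA)[shared, shared]
  b <- as.matrix(dmB)[shared, shared]
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort("zero variance in a distance triangle: correlation undefined")
  }
  pairs <- which(ut, arr.ind = TRUE)
  structure(
    list(r = cor(va, vb), n_pairs = length(va),
         shared_taxa = length(shared),
         pairs = tibble(taxon_a = shared[pairs[, "row"]],
                        taxon_b = shared[pairs[, "col"]],
                        dist_a = va, dist_b = vb)),
    class = "mirror_tree_score"
  )
}

#' @export
print.mirror_tree_score <- function(x, ...) {
  cat(sprintf("<mirror_tree_score> r = %.4f over %d pairs (%d shared taxa)\n",
              x$r, x$n_pairs, x$shared_taxa))
  invisible(x)
}

#' @export
glance.mirror_tree_score <- function(x, ...) {
  tibble(r = x$r, n_pairs = x$n_pairs, shared_taxa = x$shared_taxa)
}

#' @export
tidy.mirror_tree_score <- function(x, ...) x$pairs

#' Plot the paired distances behind a mirror-tree score
#'
#' @param object A [mirror_tree_score] object.
#' @param ... Unused.
#' @return A ggplot scatter plot of the two upper triangles.
#' @export
autoplot.mirror_tree_score <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$dist_a, y = .data$dist_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "distance (protein A)", y = "distance (protein B)",
                  title = sprintf("mirror-tree r = %.3f", object$r)) +
    ggplot2::theme_minimal()
}

#' Concatenate two alignments over their shared taxa
#'
#' Rows are joined per shared taxon, A's columns then B's. Taxa absent from
#' either input are dropped (count reported).
#'
#' @param alnA,alnB Alignment tibbles sharing at least 4 taxa.
#' @return The concatenated alignment tibble.
#' @export
concatenate_alignments <- function(alnA, alnB) {
  shared <- sort(intersect(alnA$taxon, alnB$taxon))
  if (length(shared) < 4L) abort("fewer than 4 shared taxa")
  dropped <- length(union(alnA$taxon, alnB$taxon)) - length(shared)
  if (dropped > 0L) inform(sprintf("dropped %d taxa absent from one input",
                                   dropped))
  protein_alignment(
    shared,
    paste0(alnA$seq[match(shared, alnA$taxon)],
           alnB$seq[match(shared, alnB$taxon)])
  )
}
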