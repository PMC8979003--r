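sim_with_calls <- function(seed = 7, ...) {
  sim <- simulate_genome(seed = seed, ...)
  pr <- find_promoters(sim$genome, sim$annotation)
  tm <- find_terminators(sim$genome, sim$annotation)
  list(sim = sim, pr = pr, tm = tm,
       units = segment_units(sim$annotation, pr, tm))
}

test_that("segmentation recovers the planted unit partition and the reference map", {
  x <- sim_with_calls(7)
  got <- lapply(x$units$genes, as.character)
  want <- lapply(x$sim$truth$unit_partition$genes, as.character)
  expect_setequal(vapply(got, paste, "", collapse = "-"),
                  vapply(want, paste, "", collapse = "-"))
  conc <- compare_to_reference(x$units, reference_unit_map())
  expect_equal(conc$n_predicted, 6L)
  expect_equal(conc$n_reference, 6L)
  expect_equal(conc$exact_matches, 6L)
  expect_equal(conc$gene_level_jaccard, 1)
})

test_that("a single promoter yields one unit holding every top-level gene", {
  x <- sim_with_calls(8, n_promoter_regions = 1)
  expect_equal(nrow(x$units), 1L)
  n_top <- sum(is.na(x$sim$annotation$parent))
  expect_equal(length(x$units$genes[[1]]), n_top)
  expect_error(segment_units(x$sim$annotation, x$pr[0, ]), "find_promoters")
})

test_that("every top-level gene belongs to exactly one unit, in circle order", {
  x <- sim_with_calls(19)
  all_genes <- unlist(x$units$genes)
  top <- x$sim$annotation$name[is.na(x$sim$annotation$parent)]
  expect_setequal(all_genes, top)
  expect_equal(anyDuplicated(all_genes), 0L)
  # concatenated unit gene order equals annotation circle order up to rotation
  circ <- top[order(x$sim$annotation$start[match(top, x$sim$annotation$name)])]
  i <- match(all_genes[1], circ)
  expect_equal(all_genes, circ[((i - 1 + seq_along(circ) - 1) %% length(circ)) + 1])
})

test_that("punctuation maturation excises tRNAs and tiles each unit exactly", {
  x <- sim_with_calls(7)
  mt <- mature_transcripts(x$units, x$sim$annotation)
  for (u in split(mt, mt$unit)) {
    u <- u[order(u$seg_start), ]
    expect_equal(u$seg_start, c(0, head(u$seg_end, -1)))
    lab <- u$unit[1]
    expect_equal(max(u$seg_end), x$units$length_bp[x$units$label == lab])
  }
  # every tRNA is its own product spanning exactly its gene
  trnas <- mt[mt$kind == "tRNA", ]
  ann <- x$sim$annotation
  for (i in seq_len(nrow(trnas))) {
    gene <- trnas$genes[[i]]
    expect_length(gene, 1L)
    expect_equal(trnas$start[i], ann$start[ann$name == gene])
    expect_equal(trnas$end[i], ann$end[ann$name == gene])
  }
})

test_that("co-transcribed mRNA-tRNA pairs and nested genes mature as published", {
  x <- sim_with_calls(7)
  mt <- mature_transcripts(x$units, x$sim$annotation)
  iv <- mt[mt$unit == "IV" & mt$kind != "spacer", ]
  expect_equal(sort(unlist(iv$genes)), c("cox1", "trnR2"))
  expect_setequal(iv$kind, c("mRNA", "tRNA"))
  one <- mt[mt$unit == "I", ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$kind, "rRNA")
  expect_setequal(one$genes[[1]], c("rnl", "rps3"))
  expect_true("TSS" %in% one$signals_used[[1]])
})

test_that("a unit without tRNAs or terminator is one mature transcript", {
  ann <- annotation(
    tibble::tibble(name = c("a", "b"), kind = "mRNA",
                   start = c(100L, 400L), end = c(300L, 600L), strand = "+"),
    genome_length = 1000L)
  pr <- tibble::tibble(upstream_gene = "b", downstream_gene = "a",
                       position = 39L, strand = "+", matched = "ATAGTTATTAT",
                       mismatches = 0L, score = NA_real_, tss = 50L)
  u <- segment_units(ann, pr)
  mt <- mature_transcripts(u, ann)
  expect_equal(nrow(mt), 1L)
  expect_equal(mt$seg_start, 0)
  expect_equal(mt$seg_end, u$length_bp)
})

test_that("5' UTR lengths recover planted values and respect the mRNA contract", {
  x <- sim_with_calls(7)
  first <- vapply(x$units$genes, function(g) g[1], "")
  kinds <- x$sim$annotation$kind[match(first, x$sim$annotation$name)]
  utr <- utr5_length(x$units[kinds == "mRNA", ], x$sim$annotation)
  m <- merge(as.data.frame(utr), as.data.frame(x$sim$truth$utr5),
             by = "first_gene")
  expect_gt(nrow(m), 0L)
  expect_equal(m$utr5.x, m$utr5.y)
  expect_error(utr5_length(x$units[kinds == "rRNA", ], x$sim$annotation),
               "not an mRNA")
})

test_that("a tss placed exactly at the start codon gives a zero-length UTR", {
  ann <- annotation(
    tibble::tibble(name = "m", kind = "mRNA", start = 50L, end = 200L,
                   strand = "+"),
    genome_length = 500L)
  u <- tibble::tibble(label = "I", genes = list("m"), tss = 50L,
                      n_genes = 1L, length_bp = 150L)
  expect_equal(utr5_length(u, ann)$utr5, 0L)
})

test_that("unit concordance scores a hand-worked split case", {
  ref <- tibble::tibble(label = c("R1", "R2"),
                        genes = list(c("a", "b", "c"), "d"))
  pred <- tibble::tibble(label = c("P1", "P2", "P3"),
                         genes = list("a", c("b", "c"), "d"))
  conc <- compare_to_reference(pred, ref)
  expect_equal(conc$n_predicted, 3L)
  expect_equal(conc$n_reference, 2L)
  expect_equal(conc$exact_matches, 1L)        # only d-d is identical
  expect_equal(conc$gene_level_jaccard, (1 + 2 / 3) / 2)
})

test_that("unit labelling starts at the rnl-bearing unit and survives rotation", {
  x <- sim_with_calls(11)
  expect_true("rnl" %in% x$units$genes[[which(x$units$label == "I")]])
  rot <- rotate_genome(x$sim$genome, 14000L, x$sim$annotation)
  pr2 <- find_promoters(rot$genome, rot$annotation)
  tm2 <- find_terminators(rot$genome, rot$annotation)
  u2 <- segment_units(rot$annotation, pr2, tm2)
  expect_equal(lapply(x$units$genes, c), lapply(u2$genes, c))
  expect_equal(x$units$length_bp, u2$length_bp)
})
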