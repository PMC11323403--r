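test_that("outgroup parsimony column rules call the right lineage", {
  # columns: (in1, in2, out) at positions 0..3
  aln <- stack_trio_alignment("AGGT", "GGGT", "GGAT")
  ev <- infer_substitutions(aln, anchor_offset = 0L, source_id = "x")
  # col 1: (A,G,G) -> ingroup1 G->A; col 3: (G,G,A) -> no call (a == b)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$lineage, "ingroup1")
  expect_identical(ev$from_base, "G")
  expect_identical(ev$to_base, "A")
  expect_identical(ev$rel_pos, 0L)
  expect_identical(ev$klass, "SW")

  amb <- stack_trio_alignment("A", "G", "C")
  expect_identical(nrow(infer_substitutions(amb, 0L)), 0L)

  gapn <- structure(list(gapped_in1 = "A-NT", gapped_in2 = "AGNT",
                         gapped_out = "AGNA",
                         pairwise_identities = c(in1_in2 = 1, in1_out = 1,
                                                 in2_out = 1),
                         columns = 4L, score = NA_real_),
                    class = "trio_alignment")
  expect_identical(nrow(infer_substitutions(gapn, 0L)), 0L)
})

test_that("event positions use each ingroup's ungapped coordinates", {
  aln <- structure(list(
    gapped_in1 = "AC-GTA",   # ungapped: ACGTA
    gapped_in2 = "ACTGTG",   # ungapped: ACTGTG
    gapped_out = "ACTGTA",
    pairwise_identities = c(in1_in2 = 0.6, in1_out = 0.6, in2_out = 1),
    columns = 6L, score = NA_real_), class = "trio_alignment")
  ev <- infer_substitutions(aln, anchor_offset = 0L)
  # final column: a = A, b = G, o = A -> ingroup2 A->G at its ungapped pos 5
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$lineage, "ingroup2")
  expect_identical(ev$rel_pos, 5L)
  expect_identical(ev$from_base, "A")
  expect_identical(ev$to_base, "G")
})

test_that("CpG context reflects the inferred ancestral sequence", {
  # in1 TG, in2 CG, out CG: ingroup1 event C->T whose ancestral context is CG
  aln <- stack_trio_alignment("TGAA", "CGAA", "CGAA")
  ev <- infer_substitutions(aln, 0L)
  expect_true(ev$cpg_context)
  # in1 TA: ancestral CA is not a CpG
  aln2 <- stack_trio_alignment("TAAA", "CAAA", "CAAA")
  ev2 <- infer_substitutions(aln2, 0L)
  expect_false(ev2$cpg_context)
  # ancestral reconstruction reverts the event
  expect_identical(infer_ancestral_sequence(aln, ev, "ingroup1"), "CGAA")
})

test_that("net GC change counts WS minus SW and conserves totals", {
  ev <- tibble::tibble(
    source_id = "g", rel_pos = c(0L, 0L, 0L),
    lineage = "ingroup1",
    from_base = c("A", "C", "A"), to_base = c("G", "T", "T"),
    cpg_context = FALSE,
    klass = c("WS", "SW", "WW"))
  s <- net_gc_change_series(ev, span = 5, window = 1, n_sources = 1)
  expect_identical(s$value[s$offset == 0], 0)

  empty <- ev[0, ]
  s0 <- net_gc_change_series(empty, span = 5, window = 1, n_sources = 3)
  expect_true(all(s0$value == 0))

  withr::local_seed(18)
  big <- tibble::tibble(
    source_id = "g",
    rel_pos = sample(-50:49, 200, TRUE), lineage = "ingroup1",
    from_base = "A", to_base = "G", cpg_context = FALSE,
    klass = sample(c("WS", "SW", "SS", "WW"), 200, TRUE))
  sb <- net_gc_change_series(big, span = 50, window = 100, n_sources = 7)
  total <- sum(attr(sb, "raw")) * 7
  expect_equal(total, sum(big$klass == "WS") - sum(big$klass == "SW"))
  expect_error(net_gc_change_series(dplyr::mutate(big, rel_pos = 1000L),
                                    span = 50, window = 1, n_sources = 1),
               "span")
})

test_that("rate series divide by ancestral base counts, NA when absent", {
  ev <- tibble::tibble(source_id = "g", rel_pos = 0L, lineage = "ingroup1",
                       from_base = "A", to_base = "G", cpg_context = FALSE,
                       klass = "WS")
  counts <- tibble::tibble(offset = -1:1, A = c(10L, 10L, 0L),
                           C = 0L, G = c(0L, 0L, 5L), T = 0L)
  s <- substitution_rate_series(ev, counts, "A", "G", window = 1)
  expect_identical(attr(s, "raw"), c(0, 0.1, NA))
  expect_error(
    substitution_rate_series(dplyr::mutate(ev, rel_pos = 99L), counts,
                             "A", "G"),
    "mismatch")
})

test_that("GC4 site finding matches the codon table", {
  expect_identical(find_gc4_sites("ATGGGAGCT"), c(5L, 8L))
  expect_identical(find_gc4_sites("ATGAAA"), integer(0))
  expect_error(find_gc4_sites("TTGAAA"), "ATG")
  expect_error(find_gc4_sites("ATGAA"), "divisible")

  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T")) {
    for (b3 in c("A", "C", "G", "T")) {
      codon <- paste0(b1, b2, b3)
      got <- 5L %in% find_gc4_sites(paste0("ATG", codon))
      expect_identical(got, brute_is_fourfold(codon), info = codon)
    }
  }
})

test_that("ORF-binned net GC places planted events in their bins", {
  orfs <- tibble::tibble(source_id = c("g1", "g2"), orf_length = c(400L, 400L))
  none <- orf_binned_net_gc(tibble::tibble(source_id = character(),
                                           pos = integer(),
                                           klass = character()), orfs)
  expect_true(all(none$value == 0))
  expect_identical(nrow(none), 40L)

  ev <- tibble::tibble(source_id = "g1", pos = 3L, klass = "WS")
  p <- orf_binned_net_gc(ev, orfs)
  expect_identical(p$value[1], 0.5)  # +1 in g1, 0 in g2
  expect_true(all(p$value[-1] == 0))
})

test_that("gc4_only keeps only events at ancestral fourfold sites", {
  orfs <- tibble::tibble(source_id = "g1", orf_length = 9L,
                         ancestral_orf = "ATGGGAAAA")
  ev <- tibble::tibble(source_id = "g1", pos = c(5L, 8L), klass = "WS")
  all_ev <- orf_binned_net_gc(ev, orfs)
  gc4_ev <- orf_binned_net_gc(ev, orfs, gc4_only = TRUE)
  expect_equal(sum(all_ev$value), 2)
  expect_equal(sum(gc4_ev$value), 1)  # GGA is fourfold, AAA is not
})

test_that("per-exon counts are confined to the chosen coding exon", {
  exons <- tibble::tibble(start = c(0L, 100L, 200L, 300L, 400L),
                          end = c(50L, 150L, 250L, 350L, 450L))
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "c", strand = "+", tss = 0L,
    gene_start = 0L, gene_end = 450L, exons = list(exons),
    cds_start = 10L, cds_end = 430L,
    transcripts = list(tibble::tibble(transcript_id = "t", weight = 1,
                                      tpm = 1)))
  emap <- orf_exon_map(genes)
  expect_identical(max(emap$exon_index), 5L)
  # exon 1 covers ORF [0, 40), exon 2 [40, 90)
  ev <- tibble::tibble(source_id = "g1", pos = c(45L, 60L),
                       klass = c("WS", "SW"))
  c1 <- count_events_by_exon(ev, emap, 1L)
  expect_identical(c(c1$ws, c1$sw), c(0L, 0L))
  c2 <- count_events_by_exon(ev, emap, 2L)
  expect_identical(c(c2$ws, c2$sw), c(1L, 1L))

  few <- dplyr::mutate(emap[emap$exon_index <= 3, ], n_coding_exons = 3L)
  c3 <- count_events_by_exon(ev, few, 1L)
  expect_identical(nrow(c3), 0L)
  expect_match(attr(c3, "skipped")$reason, "fewer than 4")
})

test_that("inference recovers single-hit truth events exactly", {
  withr::local_seed(19)
  m <- mutation_model()
  loci <- simulate_trio_set(30, 2000, m, c(0.002, 0.002, 0.004), seed = 20)
  res <- call_trio_substitutions(loci, band = 50)
  audit <- audit_inference(loci, res$events)
  expect_identical(audit$false_at_single_hit, 0L)
  expect_identical(audit$missed_at_single_hit, 0L)
  expect_gt(audit$n_truth_single, 10L)
})
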