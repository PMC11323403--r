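test_that("CpG context classification works on the reference strand", {
  genome <- c(c = "ACGT")
  expect_true(classify_cpg_context(genome, "c", 2, "C"))   # C followed by G
  expect_true(classify_cpg_context(genome, "c", 3, "G"))   # G preceded by C
  expect_false(classify_cpg_context(genome, "c", 1, "A"))
  expect_false(classify_cpg_context(c(c = "ATAT"), "c", 2, "T"))
  # contig edges: missing neighbor counts as non-CpG
  expect_false(classify_cpg_context(c(c = "CG"), "c", 2, "G") &&
                 classify_cpg_context(c(c = "GC"), "c", 1, "G"))
  expect_true(classify_cpg_context(c(c = "CG"), "c", 1, "C"))
  expect_error(classify_cpg_context(genome, "c", 1, "G"), "does not match")
})

dnm_fixture <- function() {
  withr::local_seed(21)
  s <- random_dna(20000)
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "c", strand = c("+", "-"),
    tss = c(5000L, 15000L),
    gene_start = c(5000L, 12000L), gene_end = c(8000L, 15001L),
    exons = list(tibble::tibble(start = 5000L, end = 8000L),
                 tibble::tibble(start = 12000L, end = 15001L)),
    cds_start = NA_integer_, cds_end = NA_integer_,
    transcripts = list(tibble::tibble(transcript_id = "t", weight = 1,
                                      tpm = 1)))
  list(genome = c(c = s), genes = genes)
}

test_that("DNMs map to TSS offsets with strand adjustment", {
  fx <- dnm_fixture()
  s <- fx$genome[["c"]]
  at_tss <- tibble::tibble(chrom = "c", pos = 5001L,
                           ref = substr(s, 5001, 5001), alt = "N")
  at_tss$alt <- setdiff(c("A", "C", "G", "T"), at_tss$ref)[1]
  m <- map_dnms(at_tss, fx$genes, fx$genome, flank = 2500)
  expect_identical(m$gene_id, "gp")
  expect_identical(m$rel_pos, 0L)

  # 10 bp 3' of the minus-strand TSS: genomic position tss - 10
  p <- 15001L - 10L
  rec <- tibble::tibble(chrom = "c", pos = p, ref = substr(s, p, p),
                        alt = NA_character_)
  rec$alt <- setdiff(c("A", "C", "G", "T"), rec$ref)[1]
  mm <- map_dnms(rec, fx$genes, fx$genome, flank = 2500)
  expect_identical(mm$gene_id, "gm")
  expect_identical(mm$rel_pos, 10L)
  expect_identical(mm$from_base, chartr("ACGT", "TGCA", rec$ref))
  expect_identical(mm$to_base, chartr("ACGT", "TGCA", rec$alt))

  far <- tibble::tibble(chrom = "c", pos = 10000L,
                        ref = substr(s, 10000, 10000), alt = "A")
  far$alt <- setdiff(c("A", "C", "G", "T"), far$ref)[1]
  expect_identical(nrow(map_dnms(far, fx$genes, fx$genome, 2500)), 0L)
})

test_that("DNMs near two TSSs map once per gene; indels are skipped", {
  fx <- dnm_fixture()
  genes2 <- fx$genes
  genes2$tss[2] <- 6000L
  genes2$strand[2] <- "+"
  s <- fx$genome[["c"]]
  rec <- tibble::tibble(chrom = "c", pos = 5500L,
                        ref = substr(s, 5500, 5500), alt = NA_character_)
  rec$alt <- setdiff(c("A", "C", "G", "T"), rec$ref)[1]
  indel <- tibble::tibble(chrom = "c", pos = 5600L, ref = "AT", alt = "A")
  m <- map_dnms(dplyr::bind_rows(rec, indel), genes2, fx$genome, 2500)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$gene_id, c("gp", "gm"))
  expect_identical(attr(m, "n_indels_skipped"), 1L)
})

test_that("mapping is idempotent and order-invariant", {
  fx <- dnm_fixture()
  m <- mutation_model(cpg_multiplier = 1)
  dnms <- simulate_dnms(fx$genome, fx$genes, m, 500, seed = 22)
  m1 <- map_dnms(dnms, fx$genes, fx$genome, 2500)
  m2 <- map_dnms(dnms[sample(nrow(dnms)), ], fx$genes, fx$genome, 2500)
  ord <- function(x) dplyr::arrange(x, gene_id, rel_pos, to_base)
  expect_equal(as.data.frame(ord(m1)), as.data.frame(ord(m2)))
})

test_that("DNM profiles conserve totals and the CpG filter is complete", {
  fx <- dnm_fixture()
  model <- mutation_model(cpg_multiplier = 8)
  dnms <- simulate_dnms(fx$genome, fx$genes, model, 4000, seed = 23)
  mapped <- map_dnms(dnms, fx$genes, fx$genome, 2500)
  windows <- extract_anchor_window(fx$genome, fx$genes, 2500)
  counts <- anchor_base_counts(windows)

  prof <- dnm_profiles(mapped, counts, n_genes = 2, window = 100)
  total <- sum(attr(prof$net, "raw")) * 2
  expect_equal(total, sum(mapped$klass == "WS") - sum(mapped$klass == "SW"))

  filt <- dnm_profiles(mapped, counts, n_genes = 2, window = 100,
                       exclude_cpg_transitions = TRUE)
  leftover <- dplyr::filter(
    filt$mapped, cpg_context,
    (from_base == "C" & to_base == "T") | (from_base == "G" & to_base == "A"))
  expect_identical(nrow(leftover), 0L)
  total_f <- sum(attr(filt$net, "raw")) * 2
  expect_equal(total_f,
               sum(filt$mapped$klass == "WS") - sum(filt$mapped$klass == "SW"))
})

test_that("a single CpG C>T contributes -1 with the filter off, 0 with it on", {
  mapped <- tibble::tibble(gene_id = "g", rel_pos = 0L, from_base = "C",
                           to_base = "T", cpg_context = TRUE, klass = "SW")
  counts <- tibble::tibble(offset = -2:1, A = 5L, C = 5L, G = 5L, T = 5L)
  off <- dnm_profiles(mapped, counts, n_genes = 1, window = 1)
  expect_identical(off$net$value[off$net$offset == 0], -1)
  on <- dnm_profiles(mapped, counts, n_genes = 1, window = 1,
                     exclude_cpg_transitions = TRUE)
  expect_true(all(on$net$value == 0))
})
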