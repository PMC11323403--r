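test_that("select_best_tss picks by score, then 5'-most TSS, then id", {
  tx <- tibble::tibble(transcript_id = c("t1", "t2"), tss = c(100, 200),
                       score = c(5, 9))
  expect_identical(select_best_tss(tx), "t2")
  expect_identical(select_best_tss(tx[1, ]), "t1")

  tie <- tibble::tibble(transcript_id = c("t1", "t2"), tss = c(150, 100),
                        score = c(3, 3))
  expect_identical(select_best_tss(tie, strand = "+"), "t2")
  expect_identical(select_best_tss(tie, strand = "-"), "t1")

  id_tie <- tibble::tibble(transcript_id = c("tB", "tA"), tss = c(50, 50),
                           score = c(1, 1))
  expect_identical(select_best_tss(id_tie), "tA")
  expect_error(select_best_tss(tie[0, ]), "empty")
  expect_error(select_best_tss(dplyr::mutate(tx, score = c(-1, 2))), ">= 0")
})

plus_minus_genes <- function(tss_plus = 5000, tss_minus = 5000) {
  tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "c", strand = c("+", "-"),
    tss = c(tss_plus, tss_minus),
    gene_start = c(tss_plus, 2000), gene_end = c(8000, tss_minus + 1),
    exons = list(tibble::tibble(start = tss_plus, end = 8000),
                 tibble::tibble(start = 2000, end = tss_minus + 1)),
    cds_start = NA_integer_, cds_end = NA_integer_,
    transcripts = list(tibble::tibble(transcript_id = "t", weight = 1,
                                      tpm = 1))
  )
}

test_that("anchor windows follow the stated coordinate conventions", {
  withr::local_seed(6)
  s <- random_dna(12000)
  genome <- c(c = s)
  genes <- plus_minus_genes()
  w <- extract_anchor_window(genome, genes, flank = 2)
  # plus strand: genomic [4998, 5002), anchor at the TSS base
  expect_identical(w$sequence[1], substr(s, 4999, 5002))
  expect_identical(w$anchor_offset[1], 2L)
  expect_identical(substr(w$sequence[1], 3, 3), substr(s, 5001, 5001))
  # minus strand: reverse complement of genomic [4999, 5003)
  expect_identical(w$sequence[2], revcomp(substr(s, 5000, 5003)))
  expect_identical(substr(w$sequence[2], 3, 3),
                   revcomp(substr(s, 5001, 5001)))
})

test_that("a hand-checkable slice comes out in transcript orientation", {
  genome <- c(c = "AAAACGTAAAA")
  genes <- plus_minus_genes(tss_plus = 4)[1, ]
  w <- extract_anchor_window(genome, genes, flank = 3)
  expect_identical(w$sequence, "AAACGT")
  expect_identical(substr(w$sequence, w$anchor_offset + 1,
                          w$anchor_offset + 1), "C")
})

test_that("out-of-bounds windows are skipped with a logged reason", {
  genome <- c(c = strrep("A", 1000))
  genes <- plus_minus_genes(tss_plus = 100)[1, ]
  w <- extract_anchor_window(genome, genes, flank = 500)
  expect_identical(nrow(w), 0L)
  expect_identical(attr(w, "skipped")$reason, "window out of bounds")
})

test_that("minus-strand windows round-trip back to the genomic slice", {
  withr::local_seed(7)
  s <- random_dna(12000)
  genome <- c(c = s)
  genes <- plus_minus_genes()[2, ]
  flank <- 100
  w <- extract_anchor_window(genome, genes, flank = flank)
  back <- revcomp(w$sequence)
  expect_identical(back, substr(s, 5000 - flank + 2, 5001 + flank))
})

make_eib_gene <- function(strand, s_len = 20000) {
  L <- 40L
  if (strand == "+") {
    exons <- tibble::tibble(start = c(1000L, 1000L + L + 200L),
                            end = c(1000L + L, 1000L + L + 500L))
    tss <- 1000L
  } else {
    exons <- tibble::tibble(start = c(500L, 3000L),
                            end = c(900L, 3000L + L))
    tss <- 3000L + L - 1L
  }
  tibble::tibble(
    gene_id = paste0("g", strand), chrom = "c", strand = strand, tss = tss,
    gene_start = min(exons$start), gene_end = max(exons$end),
    exons = list(exons), cds_start = NA_integer_, cds_end = NA_integer_,
    transcripts = list(tibble::tibble(transcript_id = "t", weight = 1,
                                      tpm = 1)))
}

test_that("EIB regions are size-matched and contiguous on both strands", {
  withr::local_seed(8)
  s <- random_dna(20000)
  genome <- c(c = s)
  for (strand in c("+", "-")) {
    gene <- make_eib_gene(strand)
    r <- extract_eib_regions(genome, gene)
    L <- r$first_exon_length
    expect_identical(nchar(r$upstream), 2L * L)
    expect_identical(nchar(r$exon1), L)
    expect_identical(nchar(r$intron1_prefix), L)
    concat <- paste0(r$upstream, r$exon1, r$intron1_prefix)
    if (strand == "+") {
      expect_identical(concat, substr(s, 1000 - 2 * L + 1, 1000 + 2 * L))
    } else {
      ex_end <- 3000 + L
      expect_identical(concat,
                       revcomp(substr(s, ex_end - 2 * L + 1, ex_end + 2 * L)))
    }
  }
})

test_that("EIB extraction skips degenerate genes with reasons", {
  genome <- c(c = strrep("ACGT", 5000))
  single <- make_eib_gene("+")
  single$exons[[1]] <- single$exons[[1]][1, ]
  r <- extract_eib_regions(genome, single)
  expect_identical(nrow(r), 0L)
  expect_identical(attr(r, "skipped")$reason, "no EIB")

  short_intron <- make_eib_gene("+")
  short_intron$exons[[1]]$start[2] <- short_intron$exons[[1]]$end[1] + 5L
  r2 <- extract_eib_regions(genome, short_intron)
  expect_match(attr(r2, "skipped")$reason, "intron")
})

test_that("intergenic sampling respects buffers, disjointness and the seed", {
  withr::local_seed(9)
  s <- random_dna(1000000)
  genome <- c(c = s)
  empty <- sample_intergenic(genome, place_genes(1000, gene_plan(0)), 0, 100)
  expect_identical(nrow(empty), 0L)

  genes <- tibble::tibble(
    gene_id = "g1", chrom = "c", strand = "+", tss = 500000L,
    gene_start = 500000L, gene_end = 520000L,
    exons = list(tibble::tibble(start = 500000L, end = 520000L)),
    cds_start = NA_integer_, cds_end = NA_integer_,
    transcripts = list(tibble::tibble(transcript_id = "t", weight = 1,
                                      tpm = 1)))
  r <- sample_intergenic(genome, genes, 50, 2000, buffer = 10000, seed = 3)
  expect_identical(nrow(r), 50L)
  ends <- r$start + 2000
  expect_true(all(ends <= 500000 - 10000 | r$start >= 520000 + 10000))
  ord <- order(r$start)
  expect_true(all(r$start[ord][-1] >= ends[ord][-50]))
  r2 <- sample_intergenic(genome, genes, 50, 2000, buffer = 10000, seed = 3)
  expect_identical(r, r2)

  # gene-free chromosome: 100 disjoint 5 kb regions fit in 1 Mb
  r3 <- sample_intergenic(genome, genes[0, ], 100, 5000, seed = 4)
  expect_identical(nrow(r3), 100L)
})

test_that("gc_match reproduces the target GC histogram exactly", {
  pool1 <- tibble::tibble(id = "r1", gc = 0.40)
  expect_identical(gc_match(pool1, 0.40)$id, "r1")
  expect_identical(nrow(gc_match(pool1, numeric(0))), 0L)

  withr::local_seed(10)
  pool <- tibble::tibble(id = sprintf("r%04d", 1:2000),
                         gc = pmin(pmax(rnorm(2000, 0.45, 0.08), 0), 1))
  target <- pmin(pmax(rnorm(200, 0.45, 0.05), 0), 1)
  got <- tryCatch(gc_match(pool, target, seed = 5), error = function(e) NULL)
  if (!is.null(got)) {
    expect_identical(table(floor(got$gc / 0.01)), table(floor(target / 0.01)))
    expect_identical(anyDuplicated(got$id), 0L)
  } else {
    succeed("pool undersupplied for this draw; error path covered below")
  }

  poor <- tibble::tibble(id = c("a", "b"), gc = c(0.10, 0.90))
  expect_error(gc_match(poor, c(0.50)), "undersupplied")
})
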