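test_that("extreme background GC forces the base alphabet", {
  all_gc <- simulate_genome_sequence(genome_spec("c", 500, 1.0, seed = 1))
  expect_match(all_gc, "^[GC]+$")
  all_at <- simulate_genome_sequence(genome_spec("c", 500, 0.0, seed = 1))
  expect_match(all_at, "^[AT]+$")
})

test_that("realized GC fraction stays inside the 99.9% binomial band", {
  n <- 100000
  s <- simulate_genome_sequence(genome_spec("c", n, 0.41, seed = 11))
  gc_count <- stringr::str_count(s, "[GC]")
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.41)
  expect_gte(gc_count, bounds[1])
  expect_lte(gc_count, bounds[2])
})

test_that("sequence generation is deterministic in the seed", {
  spec <- genome_spec("c", 2000, 0.41, seed = 3)
  expect_identical(simulate_genome_sequence(spec),
                   simulate_genome_sequence(spec))
  other <- simulate_genome_sequence(genome_spec("c", 2000, 0.41, seed = 4))
  expect_false(identical(simulate_genome_sequence(spec), other))
})

test_that("planted peaks raise local GC around their centers", {
  spec <- genome_spec("c", 20000, 0.41, seed = 5)
  peaks <- tibble::tibble(position = 10000, amplitude = 0.4, sigma = 300,
                          center_offset = 0)
  s <- simulate_genome_sequence(spec, peaks)
  center_gc <- gc_fraction(substr(s, 9800, 10200))
  flank_gc <- gc_fraction(substr(s, 1, 4000))
  expect_gt(center_gc, flank_gc + 0.2)
})

test_that("invalid specs and peaks are rejected", {
  expect_error(genome_spec("c", 0), "length")
  expect_error(genome_spec("c", 10, background_gc = 1.2), "background_gc")
  expect_error(gc_peak_spec(sigma = 0), "sigma")
  spec <- genome_spec("c", 100, 0.4, seed = 1)
  bad <- tibble::tibble(position = 200, amplitude = 0.1, sigma = 10,
                        center_offset = 0)
  expect_error(simulate_genome_sequence(spec, bad), "within")
})

test_that("place_genes honors the plan structurally", {
  expect_identical(nrow(place_genes(10000, gene_plan(0))), 0L)

  plan2 <- gene_plan(2, min_intergenic_gap = 1000)
  g2 <- place_genes(100000, plan2, seed = 2)
  expect_gte(g2$gene_start[2] - g2$gene_end[1], 1000)

  plan <- gene_plan(50)
  genes <- place_genes(1e7, plan, seed = 9)
  expect_identical(nrow(genes), 50L)
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(all(ex$start >= genes$gene_start[i]))
    expect_true(all(ex$end <= genes$gene_end[i]))
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end > ex$start))
    n_ex <- nrow(ex)
    expect_gte(n_ex, plan$n_exons_range[1])
    expect_lte(n_ex, plan$n_exons_range[2])
    # exons do not overlap
    expect_true(all(ex$start[-1] >= ex$end[-n_ex]))
    # CDS inside the exon union and a multiple of 3 when spliced
    cds_len <- sum(pmax(0, pmin(ex$end, genes$cds_end[i]) -
                          pmax(ex$start, genes$cds_start[i])))
    expect_identical(cds_len %% 3, 0)
    expect_gte(genes$cds_start[i], genes$gene_start[i])
    expect_lte(genes$cds_end[i], genes$gene_end[i])
    # TSS is the 5'-most transcribed base in transcript orientation
    if (genes$strand[i] == "+") {
      expect_identical(genes$tss[i], ex$start[1])
    } else {
      expect_identical(genes$tss[i], ex$end[n_ex] - 1L)
    }
  }
  # genes never overlap
  expect_true(all(genes$gene_start[-1] >= genes$gene_end[-50]))
})

test_that("infeasible plans fail with an explicit constraint message", {
  expect_error(place_genes(5000, gene_plan(10, min_intergenic_gap = 5000)),
               "min_intergenic_gap")
})

test_that("FASTA + GTF round trip reproduces the gene set and sequence", {
  withr::local_seed(1)
  g <- make_test_genome(n_genes = 8, length = 150000)
  fa <- withr::local_tempfile(fileext = ".fa")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_genome_fasta(g$sequence, fa)
  write_genes_gtf(g$genes, gtf)
  expect_identical(read_genome_fasta(fa), g$sequence)
  back <- read_genes_gtf(gtf)
  expect_identical(as.data.frame(back), as.data.frame(g$genes))

  # same seed, byte-identical FASTA
  fa2 <- withr::local_tempfile(fileext = ".fa")
  g2 <- make_test_genome(n_genes = 8, length = 150000)
  write_genome_fasta(g2$sequence, fa2)
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("stamped start codons make every gene ORF-ready", {
  g <- make_test_genome(n_genes = 6, length = 120000)
  for (i in seq_len(nrow(g$genes))) {
    gene <- g$genes[i, ]
    orf <- spliced_cds(g$sequence, gene)
    expect_identical(substr(orf, 1, 3), "ATG")
    expect_identical(nchar(orf) %% 3L, 0L)
  }
})

test_that("the TSS score table carries one positive score per transcript", {
  g <- make_test_genome(n_genes = 5, length = 100000)
  expect_identical(nrow(g$tss_scores), 5L)
  expect_true(all(g$tss_scores$tpm_score > 0))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tss_scores(g$tss_scores, p)
  expect_equal(as.data.frame(read_tss_scores(p)),
               as.data.frame(g$tss_scores))
})
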