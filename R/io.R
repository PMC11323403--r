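#' Write a genome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param sequence Named character vector (names are chromosome names).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequence, path) {
  dna <- Biostrings::DNAStringSet(sequence)
  Biostrings::writeXStringSet(dna, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  # drop any description after the first whitespace
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Write gene models to GTF
#'
#' Emits gene, transcript, exon, and CDS features (1-based, inclusive, per the
#' GTF convention; internal coordinates are 0-based half-open and converted at
#' this boundary). Isoform weights and scores ride along as `weight` and `tpm`
#' attributes on transcript features so that a written-then-reparsed gene set
#' is identical.
#'
#' @param genes Gene model tibble as produced by [place_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  feats <- purrr::pmap(genes, function(gene_id, chrom, strand, tss, gene_start,
                                       gene_end, exons, cds_start, cds_end,
                                       transcripts, ...) {
    tx <- transcripts$transcript_id[1]
    dplyr::bind_rows(
      tibble(type = "gene", start = gene_start, end = gene_end,
             transcript_id = NA_character_, weight = NA_real_, tpm = NA_real_),
      tibble(type = "transcript", start = gene_start, end = gene_end,
             transcript_id = transcripts$transcript_id,
             weight = transcripts$weight, tpm = transcripts$tpm),
      tibble(type = "exon", start = exons$start, end = exons$end,
             transcript_id = tx, weight = NA_real_, tpm = NA_real_),
      tibble(type = "CDS", start = cds_start, end = cds_end,
             transcript_id = tx, weight = NA_real_, tpm = NA_real_)
    ) |>
      dplyr::mutate(gene_id = gene_id, chrom = chrom, strand = strand)
  }) |> dplyr::bind_rows()

  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand
  )
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$gene_id <- feats$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feats$transcript_id
  S4Vectors::mcols(gr)$weight <- feats$weight
  S4Vectors::mcols(gr)$tpm <- feats$tpm
  S4Vectors::mcols(gr)$phase <- ifelse(feats$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Inverse of [write_genes_gtf()]: reconstructs the gene model tibble
#' (0-based half-open coordinates, exons in genomic order).
#'
#' @param path GTF file.
#' @return Gene model tibble (see [place_genes()]).
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr)) |>
    dplyr::mutate(start0 = as.integer(.data$start - 1L),
                  end0 = as.integer(.data$end),
                  strand = as.character(.data$strand),
                  seqnames = as.character(.data$seqnames))
  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::arrange(.data$start0)
  purrr::pmap(
    list(genes$gene_id, genes$seqnames, genes$strand,
         genes$start0, genes$end0),
    function(gid, chrom, strand, gstart, gend) {
      sub <- dplyr::filter(df, .data$gene_id == gid)
      ex <- dplyr::filter(sub, .data$type == "exon") |>
        dplyr::arrange(.data$start0)
      cds <- dplyr::filter(sub, .data$type == "CDS")
      tx <- dplyr::filter(sub, .data$type == "transcript")
      tss <- if (strand == "+") gstart else gend - 1L
      tibble(
        gene_id = gid, chrom = chrom, strand = strand, tss = as.integer(tss),
        gene_start = gstart, gene_end = gend,
        exons = list(tibble(start = ex$start0, end = ex$end0)),
        cds_start = if (nrow(cds)) cds$start0[1] else NA_integer_,
        cds_end = if (nrow(cds)) cds$end0[1] else NA_integer_,
        transcripts = list(tibble(
          transcript_id = tx$transcript_id,
          weight = as.numeric(tx$weight),
          tpm = as.numeric(tx$tpm)
        ))
      )
    }
  ) |> dplyr::bind_rows()
}

#' Write / read a TSS score table
#'
#' Two-column TSV (`transcript_id`, `tpm_score`) emulating a CAGE
#' tags-per-million table.
#'
#' @param scores Tibble with `transcript_id` and `tpm_score`.
#' @param path File path.
#' @return `path` (write) or the score tibble (read).
#' @export
write_tss_scores <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' @rdname write_tss_scores
#' @export
read_tss_scores <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    tpm_score = readr::col_double()
  ))
}

#' Write / read de novo mutation records
#'
#' The on-disk format is a 4-column TSV (`chrom`, `pos` 1-based, `ref`,
#' `alt`); [read_dnms()] also accepts a VCF (SNVs; other records are dropped
#' with a warning).
#'
#' @param dnms Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param path File path (`.tsv` or `.vcf`).
#' @return `path` (write) or a DNM tibble (read).
#' @export
write_dnm_tsv <- function(dnms, path) {
  readr::write_tsv(dnms[, c("chrom", "pos", "ref", "alt")], path)
  invisible(path)
}

#' @rdname write_dnm_tsv
#' @export
read_dnms <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      abort("reading VCF requires the VariantAnnotation package")
    }
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt_l <- VariantAnnotation::alt(vcf)
    alt <- vapply(as.list(alt_l), function(a) as.character(a)[1], character(1))
    keep <- nchar(ref) == 1 & nchar(alt) == 1
    if (any(!keep)) {
      warn(sprintf("dropped %d non-SNV record(s)", sum(!keep)))
    }
    tibble(
      chrom = as.character(GenomicRanges::seqnames(rr))[keep],
      pos = GenomicRanges::start(rr)[keep],
      ref = ref[keep], alt = alt[keep]
    )
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    ))
  }
}

#' Write homologous trio sequences as a FASTA triplet
#'
#' Records are named `<locus>_in1`, `<locus>_in2`, `<locus>_out`.
#'
#' @param locus A `trio_locus` (see [simulate_trio()]).
#' @param path Output FASTA.
#' @param name Locus name used in record headers.
#' @return `path`, invisibly.
#' @export
write_trio_fasta <- function(locus, path, name = "locus") {
  seqs <- c(locus$in1, locus$in2, locus$out)
  names(seqs) <- paste0(name, c("_in1", "_in2", "_out"))
  write_genome_fasta(seqs, path)
}

#' @rdname write_trio_fasta
#' @export
read_trio_fasta <- function(path) {
  seqs <- read_genome_fasta(path)
  in1 <- seqs[grepl("_in1$", names(seqs))]
  in2 <- seqs[grepl("_in2$", names(seqs))]
  out <- seqs[grepl("_out$", names(seqs))]
  if (length(in1) != 1 || length(in2) != 1 || length(out) != 1) {
    abort("expected exactly one _in1, _in2 and _out record")
  }
  list(in1 = unname(in1), in2 = unname(in2), out = unname(out),
       name = sub("_in1$", "", names(in1)))
}
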