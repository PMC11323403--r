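#' Pick the best-supported TSS among a gene's transcripts
#'
#' Returns the transcript with the highest score (e.g. CAGE tags per
#' million). Ties are broken by the 5'-most TSS in transcript orientation,
#' then by lexicographic transcript id.
#'
#' @param transcripts Tibble with columns `transcript_id`, `tss` (genomic
#'   position), `score` (>= 0).
#' @param strand Gene strand, `"+"` or `"-"` (decides which TSS is 5'-most).
#' @return The winning `transcript_id` (length-1 character).
#' @export
select_best_tss <- function(transcripts, strand = "+") {
  if (nrow(transcripts) == 0) abort("empty transcript list")
  if (any(transcripts$score < 0)) abort("scores must be >= 0")
  five_prime <- if (strand == "+") transcripts$tss else -transcripts$tss
  ord <- order(-transcripts$score, five_prime, transcripts$transcript_id)
  transcripts$transcript_id[ord[1]]
}

# fetch genomic slice [start, end) 0-based from a named genome vector
genome_slice <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

#' Extract anchored windows around TSSs
#'
#' For each gene, returns the `2 * flank` bp window centered on the TSS in
#' transcript orientation: position 0 (`anchor_offset = flank`) is the TSS
#' base itself, negative offsets run upstream. Minus-strand genes are
#' reverse-complemented so positive offsets run 5' to 3' into the gene. Genes
#' whose window exceeds the chromosome are skipped; the skip reasons are
#' attached as the `"skipped"` attribute.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene model tibble.
#' @param flank Half-window in bp.
#' @return Tibble `source_id`, `anchor_kind = "TSS"`, `sequence`,
#'   `anchor_offset`, with attribute `skipped` (tibble `gene_id`, `reason`).
#' @export
extract_anchor_window <- function(genome, genes, flank = 2500) {
  rows <- vector("list", nrow(genes))
  skipped <- list()
  for (g in seq_len(nrow(genes))) {
    chrom <- genes$chrom[g]
    clen <- nchar(genome[[chrom]])
    tss <- genes$tss[g]
    if (genes$strand[g] == "+") {
      lo <- tss - flank; hi <- tss + flank
      if (lo < 0 || hi > clen) {
        skipped <- c(skipped, list(tibble(gene_id = genes$gene_id[g],
                                          reason = "window out of bounds")))
        next
      }
      seq <- genome_slice(genome, chrom, lo, hi)
    } else {
      lo <- tss - flank + 1L; hi <- tss + flank + 1L
      if (lo < 0 || hi > clen) {
        skipped <- c(skipped, list(tibble(gene_id = genes$gene_id[g],
                                          reason = "window out of bounds")))
        next
      }
      seq <- revcomp(genome_slice(genome, chrom, lo, hi))
    }
    rows[[g]] <- tibble(source_id = genes$gene_id[g], anchor_kind = "TSS",
                        sequence = seq, anchor_offset = as.integer(flank))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Extract first-exon-normalized regions around the TSS and EIB
#'
#' With L the first-exon length (in transcript orientation), returns the 2L bp
#' immediately upstream of the TSS, the first exon (L bp), and the first L bp
#' of intron 1 — all in transcript orientation, jointly covering a contiguous
#' 4L genomic span. Genes without a first exon-intron boundary, with a first
#' intron shorter than L, or with the upstream span out of bounds are skipped
#' with a reason (attribute `"skipped"`).
#'
#' @inheritParams extract_anchor_window
#' @return Tibble `gene_id`, `upstream`, `exon1`, `intron1_prefix`,
#'   `first_exon_length`; attribute `skipped`.
#' @export
extract_eib_regions <- function(genome, genes) {
  rows <- vector("list", nrow(genes))
  skipped <- list()
  skip <- function(gid, why) tibble(gene_id = gid, reason = why)
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    ex <- genes$exons[[g]]
    chrom <- genes$chrom[g]
    clen <- nchar(genome[[chrom]])
    if (nrow(ex) < 2) { skipped <- c(skipped, list(skip(gid, "no EIB"))); next }
    if (genes$strand[g] == "+") {
      e1 <- ex[1, ]
      L <- e1$end - e1$start
      intron_len <- ex$start[2] - e1$end
      if (intron_len < L) {
        skipped <- c(skipped, list(skip(gid, "first intron shorter than first exon")))
        next
      }
      if (e1$start - 2L * L < 0) {
        skipped <- c(skipped, list(skip(gid, "upstream out of bounds")))
        next
      }
      upstream <- genome_slice(genome, chrom, e1$start - 2L * L, e1$start)
      exon1 <- genome_slice(genome, chrom, e1$start, e1$end)
      intron1 <- genome_slice(genome, chrom, e1$end, e1$end + L)
    } else {
      e1 <- ex[nrow(ex), ]  # transcript-first exon is the genomic-last one
      L <- e1$end - e1$start
      intron_len <- e1$start - ex$end[nrow(ex) - 1L]
      if (intron_len < L) {
        skipped <- c(skipped, list(skip(gid, "first intron shorter than first exon")))
        next
      }
      if (e1$end + 2L * L > clen) {
        skipped <- c(skipped, list(skip(gid, "upstream out of bounds")))
        next
      }
      upstream <- revcomp(genome_slice(genome, chrom, e1$end, e1$end + 2L * L))
      exon1 <- revcomp(genome_slice(genome, chrom, e1$start, e1$end))
      intron1 <- revcomp(genome_slice(genome, chrom, e1$start - L, e1$start))
    }
    rows[[g]] <- tibble(gene_id = gid, upstream = upstream, exon1 = exon1,
                        intron1_prefix = intron1,
                        first_exon_length = as.integer(L))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Sample random intergenic control regions
#'
#' Draws `n` mutually non-overlapping regions of the given length, each at
#' least `buffer` bp away from every annotated gene span, with the anchor at
#' the region midpoint. Placement is rejection sampling with a bounded number
#' of retries.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene model tibble (gene spans to avoid); may have zero rows.
#' @param n Number of regions.
#' @param length Region length in bp.
#' @param buffer Minimum distance from any gene span (default 10 kb, keeping
#'   controls clear of the TSS-peak shoulders that extend to ~2.5 kb).
#' @param seed Integer seed.
#' @return Tibble `source_id`, `anchor_kind = "intergenic"`, `chrom`, `start`
#'   (0-based), `sequence`, `anchor_offset`.
#' @export
sample_intergenic <- function(genome, genes, n, length, buffer = 10000,
                              seed = 1L) {
  if (n == 0) {
    return(tibble(source_id = character(), anchor_kind = character(),
                  chrom = character(), start = integer(),
                  sequence = character(), anchor_offset = integer()))
  }
  chrom <- names(genome)[1]
  clen <- nchar(genome[[chrom]])
  spans <- genes[genes$chrom == chrom, c("gene_start", "gene_end")]
  bad_lo <- spans$gene_start - buffer
  bad_hi <- spans$gene_end + buffer
  max_start <- clen - length
  if (max_start < 0) abort("region length exceeds chromosome")
  with_seed(seed, {
    chosen_lo <- integer(0)
    out <- vector("list", n)
    k <- 0L
    tries <- 0L
    max_tries <- 1000L * n
    while (k < n && tries < max_tries) {
      tries <- tries + 1L
      s <- sample.int(max_start + 1L, 1L) - 1L
      e <- s + length
      if (any(e > bad_lo & s < bad_hi)) next
      if (any(e > chosen_lo & s < chosen_lo + length)) next
      k <- k + 1L
      chosen_lo <- c(chosen_lo, s)
      out[[k]] <- tibble(
        source_id = sprintf("intergenic%04d", k),
        anchor_kind = "intergenic", chrom = chrom, start = s,
        sequence = genome_slice(genome, chrom, s, e),
        anchor_offset = as.integer(floor(length / 2))
      )
    }
    if (k < n) {
      abort(sprintf(
        "placed only %d of %d intergenic regions after %d tries (length %d, buffer %d)",
        k, n, max_tries, length, buffer))
    }
    dplyr::bind_rows(out)
  })
}

#' Select a GC-matched control set
#'
#' For every value in `target_gcs`, draws (without replacement) one pool
#' region from the pool's matching GC bin, so the selected set's per-bin GC
#' histogram equals the target's exactly.
#'
#' @param pool Tibble of candidate regions with a `gc` column (any other
#'   columns ride along).
#' @param target_gcs Numeric vector of GC fractions to match.
#' @param bin_width GC bin width (default 0.01).
#' @param seed Integer seed.
#' @return A tibble of `length(target_gcs)` rows sampled from `pool`.
#' @export
gc_match <- function(pool, target_gcs, bin_width = 0.01, seed = 1L) {
  if (length(target_gcs) == 0) return(pool[0, ])
  pool_bin <- floor(pool$gc / bin_width)
  target_bin <- floor(target_gcs / bin_width)
  need <- table(target_bin)
  have <- table(pool_bin)
  for (b in names(need)) {
    n_have <- if (b %in% names(have)) have[[b]] else 0L
    if (n_have < need[[b]]) {
      lo <- as.numeric(b) * bin_width
      abort(sprintf("GC bin [%.2f, %.2f) undersupplied: need %d, pool has %d",
                    lo, lo + bin_width, need[[b]], n_have))
    }
  }
  with_seed(seed, {
    picks <- integer(0)
    for (b in names(need)) {
      idx <- which(pool_bin == as.numeric(b))
      take <- if (length(idx) == 1L) idx else sample(idx, need[[b]])
      picks <- c(picks, take[seq_len(need[[b]])])
    }
    pool[picks, ]
  })
}

#' Spliced CDS (ORF) of a gene in transcript orientation
#'
#' Clips each exon to the CDS bounds, concatenates in transcript order, and
#' reverse-complements for minus-strand genes.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gene One-row gene model tibble.
#' @return The ORF DNA string.
#' @export
spliced_cds <- function(genome, gene) {
  ex <- gene$exons[[1]]
  idx <- if (gene$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  pieces <- character(0)
  for (j in idx) {
    s <- max(ex$start[j], gene$cds_start)
    e <- min(ex$end[j], gene$cds_end)
    if (e > s) {
      piece <- genome_slice(genome, gene$chrom, s, e)
      if (gene$strand == "-") piece <- revcomp(piece)
      pieces <- c(pieces, piece)
    }
  }
  paste(pieces, collapse = "")
}
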