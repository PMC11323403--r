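#' Specify a synthetic chromosome
#'
#' The background model draws every base independently: a base is G or C with
#' probability `background_gc` (plus any local peak contribution), and the
#' choice between G and C (or A and T) is uniform. The default background of
#' 0.41 matches the mammalian genome-wide average GC fraction.
#'
#' @param chrom_name Chromosome name used in FASTA/GTF output.
#' @param length Chromosome length in bp (> 0).
#' @param background_gc Baseline probability that a position is G or C.
#' @param seed Integer seed; the same spec always yields a byte-identical
#'   sequence.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_name = "chrS", length, background_gc = 0.41,
                        seed = 1L) {
  if (length <= 0) abort("`length` must be > 0")
  if (background_gc < 0 || background_gc > 1) {
    abort("`background_gc` must be in [0, 1]")
  }
  structure(
    list(chrom_name = chrom_name, length = as.integer(length),
         background_gc = background_gc, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Specify a Gaussian GC peak
#'
#' A peak adds `amplitude * exp(-(x - center)^2 / (2 sigma^2))` to the local
#' probability of drawing G or C, emulating the near-normal elevation of
#' GC-content observed around transcription start sites.
#'
#' @param amplitude GC probability added at the peak center.
#' @param sigma Gaussian width in bp (> 0).
#' @param center_offset Offset of the peak center from the anchor (e.g. TSS),
#'   in transcript orientation.
#' @return A `gc_peak_spec` list.
#' @export
gc_peak_spec <- function(amplitude = 0.25, sigma = 500, center_offset = 0) {
  if (sigma <= 0) abort("`sigma` must be > 0")
  structure(
    list(amplitude = amplitude, sigma = sigma,
         center_offset = as.integer(center_offset)),
    class = "gc_peak_spec"
  )
}

#' Specify a synthetic gene layout
#'
#' Genes are placed greedily left to right, separated by at least
#' `min_intergenic_gap` bp, and never overlap. Each gene receives one
#' transcript (weight 1) and a positive expression score, mimicking a CAGE
#' tags-per-million table.
#'
#' @param n_genes Number of genes to place.
#' @param first_exon_length_range Min/max first-exon length in bp. The same
#'   range is used for later exons.
#' @param n_exons_range Min/max exon count per gene.
#' @param intron_length_range Min/max intron length in bp.
#' @param min_intergenic_gap Minimum distance between gene spans (also used as
#'   the chromosome-edge margin so flanking windows stay in bounds).
#' @param strand_policy `"both"` (random strand per gene) or `"plus_only"`.
#' @return A `gene_plan` list.
#' @export
gene_plan <- function(n_genes,
                      first_exon_length_range = c(150, 600),
                      n_exons_range = c(2, 8),
                      intron_length_range = c(500, 3000),
                      min_intergenic_gap = 5000,
                      strand_policy = c("both", "plus_only")) {
  strand_policy <- match.arg(strand_policy)
  ranges <- list(first_exon_length_range, n_exons_range, intron_length_range)
  if (any(vapply(ranges, function(r) any(r <= 0) || r[2] < r[1], logical(1)))) {
    abort("all plan ranges must be positive with min <= max")
  }
  if (n_genes < 0) abort("`n_genes` must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes),
         first_exon_length_range = as.integer(first_exon_length_range),
         n_exons_range = as.integer(n_exons_range),
         intron_length_range = as.integer(intron_length_range),
         min_intergenic_gap = as.integer(min_intergenic_gap),
         strand_policy = strand_policy),
    class = "gene_plan"
  )
}

#' Generate a chromosome sequence with planted GC peaks
#'
#' Per-base independent sampling: P(G or C at x) is the background plus the
#' sum of all Gaussian peak contributions, clipped to \[0, 1\]; G vs C and A
#' vs T are chosen uniformly. Deterministic given `spec$seed`.
#'
#' @param spec A [genome_spec()].
#' @param peaks Optional tibble with columns `position` (anchor, 0-based) plus
#'   `amplitude`, `sigma`, `center_offset` (see [gc_peak_spec()]), one row per
#'   peak. `NULL` for a flat background.
#' @return A single DNA string of length `spec$length`.
#' @export
simulate_genome_sequence <- function(spec, peaks = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  L <- spec$length
  p <- rep(spec$background_gc, L)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    if (any(peaks$position < 0 | peaks$position >= L)) {
      abort("peak positions must lie within [0, length)")
    }
    for (k in seq_len(nrow(peaks))) {
      center <- peaks$position[k] + peaks$center_offset[k]
      sigma <- peaks$sigma[k]
      lo <- max(0L, floor(center - 6 * sigma))
      hi <- min(L - 1L, ceiling(center + 6 * sigma))
      if (hi < lo) next
      x <- lo:hi
      p[x + 1L] <- p[x + 1L] +
        peaks$amplitude[k] * exp(-(x - center)^2 / (2 * sigma^2))
    }
    p <- pmin(pmax(p, 0), 1)
  }
  with_seed(spec$seed, {
    strong <- runif(L) < p
    half <- runif(L) < 0.5
    base <- ifelse(strong, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    paste(base, collapse = "")
  })
}

#' Place non-overlapping gene models on a chromosome
#'
#' Greedy left-to-right placement with a random extra gap on top of
#' `min_intergenic_gap`. Minus-strand genes store exons in genomic order;
#' transcript orientation is resolved at extraction time. Each gene carries a
#' CDS whose start lies inside exon 1 and whose spliced length is divisible by
#' 3 (so ORF analyses apply without further filtering).
#'
#' @param sequence_length Chromosome length in bp.
#' @param plan A [gene_plan()].
#' @param seed Integer seed.
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based first transcribed base), `gene_start`/`gene_end` (0-based
#'   half-open span), `exons` (list of tibbles with 0-based half-open
#'   `start`/`end`, genomic order), `cds_start`/`cds_end`, and `transcripts`
#'   (list of tibbles `transcript_id`, `weight`, `tpm`).
#' @export
place_genes <- function(sequence_length, plan, seed = 1L, chrom = "chrS") {
  stopifnot(inherits(plan, "gene_plan"))
  if (plan$n_genes == 0L) return(empty_gene_tbl())
  gap <- plan$min_intergenic_gap
  with_seed(seed, {
    rows <- vector("list", plan$n_genes)
    cursor <- gap  # left margin
    for (g in seq_len(plan$n_genes)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        n_ex <- sample(plan$n_exons_range[1]:plan$n_exons_range[2], 1L)
        ex_len <- sample(plan$first_exon_length_range[1]:plan$first_exon_length_range[2],
                         n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) {
          sample(plan$intron_length_range[1]:plan$intron_length_range[2],
                 n_ex - 1L, replace = TRUE)
        } else integer(0)
        span <- sum(ex_len) + sum(in_len)
        extra <- sample.int(gap, 1L)
        start <- cursor + extra
        if (start + span + gap <= sequence_length) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place gene %d of %d: chromosome length %d too small for min_intergenic_gap %d",
          g, plan$n_genes, sequence_length, gap))
      }
      strand <- if (plan$strand_policy == "plus_only") "+" else
        sample(c("+", "-"), 1L)

      # exon genomic intervals; transcript order = genomic order on "+",
      # reversed on "-" (exons are always stored in genomic order)
      if (strand == "+") {
        gex <- ex_len; gin <- in_len
      } else {
        gex <- rev(ex_len); gin <- rev(in_len)
      }
      ex_start <- start + cumsum(c(0L, head_lengths(gex, gin)))
      exons <- tibble(start = as.integer(ex_start),
                      end = as.integer(ex_start + gex))
      tss <- if (strand == "+") start else start + span - 1L

      # CDS: start codon inside exon 1, spliced length divisible by 3
      e1_len <- ex_len[1]
      utr5 <- sample.int(max(e1_len - 30L, 1L), 1L)
      total_exonic <- sum(ex_len)
      utr3 <- sample.int(max(ex_len[n_ex] - 10L, 1L), 1L)
      cds_len <- total_exonic - utr5 - utr3
      cds_len <- max(cds_len - (cds_len %% 3L), 3L)
      cds <- tx_to_genomic_bounds(exons, strand, utr5, utr5 + cds_len)

      gene_id <- sprintf("g%04d", g)
      rows[[g]] <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        tss = as.integer(tss),
        gene_start = as.integer(start), gene_end = as.integer(start + span),
        exons = list(exons),
        cds_start = as.integer(cds[1]), cds_end = as.integer(cds[2]),
        transcripts = list(tibble(
          transcript_id = paste0(gene_id, ".1"),
          weight = 1,
          tpm = round(rlnorm(1, meanlog = 3, sdlog = 1), 4)
        ))
      )
      cursor <- start + span + gap
    }
    dplyr::bind_rows(rows)
  })
}

# interleave exon/intron lengths (transcript order) into step sizes between
# successive exon starts
head_lengths <- function(ex_len, in_len) {
  n <- length(ex_len)
  if (n == 1) return(integer(0))
  ex_len[-n] + in_len
}

# convert transcript-coordinate half-open bounds to genomic half-open bounds;
# exons are in genomic order, transcript order is reversed on "-"
tx_to_genomic_bounds <- function(exons, strand, tx_start, tx_end) {
  idx <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  tx_lens <- (exons$end - exons$start)[idx]
  offs <- cumsum(c(0L, tx_lens))
  g <- function(tx) {
    i <- findInterval(tx, offs)
    i <- min(max(i, 1L), length(idx))
    within <- tx - offs[i]
    e <- exons[idx[i], ]
    if (strand == "+") e$start + within else e$end - 1L - within
  }
  if (strand == "+") c(g(tx_start), g(tx_end - 1L) + 1L)
  else c(g(tx_end - 1L), g(tx_start) + 1L)
}

empty_gene_tbl <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    tss = integer(), gene_start = integer(), gene_end = integer(),
    exons = list(), cds_start = integer(), cds_end = integer(),
    transcripts = list()
  )
}

#' Simulate a full synthetic genome: sequence, genes, and TSS scores
#'
#' Places genes, plants one shared GC peak at every TSS, draws the sequence,
#' and (by default) stamps an ATG start codon at each CDS start so
#' downstream ORF operations apply. The companion TSS score table carries one
#' positive score per transcript.
#'
#' @param spec A [genome_spec()].
#' @param plan A [gene_plan()].
#' @param peak A [gc_peak_spec()] shared by all genes, or `NULL` for no peaks.
#' @param stamp_start_codons Write ATG (strand-aware) at each CDS start.
#' @return A list of class `synthetic_genome` with elements `sequence` (named
#'   character), `genes` (tibble), and `tss_scores` (tibble
#'   `transcript_id`, `tpm_score`).
#' @export
simulate_genome <- function(spec, plan, peak = gc_peak_spec(),
                            stamp_start_codons = TRUE) {
  genes <- place_genes(spec$length, plan, seed = spec$seed + 1L,
                       chrom = spec$chrom_name)
  peaks <- NULL
  if (!is.null(peak) && nrow(genes) > 0) {
    sign <- ifelse(genes$strand == "+", 1L, -1L)
    peaks <- tibble(
      position = genes$tss,
      amplitude = peak$amplitude,
      sigma = peak$sigma,
      center_offset = sign * peak$center_offset
    )
  }
  sequence <- simulate_genome_sequence(spec, peaks)
  if (stamp_start_codons && nrow(genes) > 0) {
    chars <- seq_chars(sequence)
    for (g in seq_len(nrow(genes))) {
      if (genes$strand[g] == "+") {
        i <- genes$cds_start[g] + 1L
        chars[i:(i + 2L)] <- c("A", "T", "G")
      } else {
        i <- genes$cds_end[g]  # 1-based index of the last CDS base
        chars[(i - 2L):i] <- c("C", "A", "T")  # revcomp of ATG
      }
    }
    sequence <- paste(chars, collapse = "")
  }
  tss_scores <- if (nrow(genes) > 0) {
    tidyr::unnest(dplyr::select(genes, "transcripts"), "transcripts") |>
      dplyr::transmute(transcript_id = .data$transcript_id,
                       tpm_score = .data$tpm)
  } else {
    tibble(transcript_id = character(), tpm_score = numeric())
  }
  structure(
    list(sequence = setNames(sequence, spec$chrom_name),
         genes = genes, tss_scores = tss_scores),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %s: %s bp, %d genes, GC %.3f\n",
              names(x$sequence), format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), gc_fraction(unname(x$sequence))))
  invisible(x)
}
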