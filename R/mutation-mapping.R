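#' Is a reference base part of a CpG dinucleotide?
#'
#' Evaluated on the reference strand: `TRUE` iff the base is a C followed by
#' G, or a G preceded by C. Missing neighbors at contig edges count as
#' non-CpG. Deamination chemistry is symmetric across the CG palindrome, so
#' reference-strand evaluation covers both strands.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref Reference base(s) (must match the genome).
#' @return Logical vector.
#' @export
classify_cpg_context <- function(genome, chrom, pos, ref) {
  purrr::pmap_lgl(list(chrom, pos, ref), function(ch, p, r) {
    s <- genome[[ch]]
    n <- nchar(s)
    if (substr(s, p, p) != r) {
      abort(sprintf("ref %s does not match genome at %s:%d", r, ch, p))
    }
    if (r == "C") p < n && substr(s, p + 1L, p + 1L) == "G"
    else if (r == "G") p > 1L && substr(s, p - 1L, p - 1L) == "C"
    else FALSE
  })
}

#' Map de novo mutations onto TSS-anchored windows
#'
#' Every single-nucleotide DNM within `flank` bp of a gene's TSS is assigned
#' to that gene with its offset and bases expressed in transcript
#' orientation (minus-strand genes complement ref/alt and negate the genomic
#' offset). A DNM within range of several TSSs maps to every such gene (one
#' record per gene). Indel records are skipped; their count is attached as
#' the `n_indels_skipped` attribute. CpG context is classified on the
#' reference strand before any strand adjustment.
#'
#' @param dnms Tibble `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genes Gene model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Half-window around the TSS (default 2500, i.e. the 5 kb
#'   window).
#' @return Tibble `gene_id`, `rel_pos`, `from_base`, `to_base`,
#'   `cpg_context`, `klass`.
#' @export
map_dnms <- function(dnms, genes, genome, flank = 2500) {
  snv <- dplyr::filter(dnms, nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  n_indels <- nrow(dnms) - nrow(snv)
  if (nrow(snv) > 0) {
    snv$cpg_context <- classify_cpg_context(genome, snv$chrom, snv$pos,
                                            snv$ref)
  }
  out <- purrr::pmap(
    genes[, c("gene_id", "chrom", "strand", "tss")],
    function(gene_id, chrom, strand, tss) {
      near <- dplyr::filter(snv, .data$chrom == !!chrom)
      pos0 <- near$pos - 1L
      rel <- if (strand == "+") pos0 - tss else tss - pos0
      keep <- rel >= -flank & rel < flank
      if (!any(keep)) return(NULL)
      near <- near[keep, ]
      rel <- rel[keep]
      from <- near$ref
      to <- near$alt
      if (strand == "-") {
        from <- chartr("ACGT", "TGCA", from)
        to <- chartr("ACGT", "TGCA", to)
      }
      tibble(gene_id = gene_id, rel_pos = as.integer(rel),
             from_base = from, to_base = to,
             cpg_context = near$cpg_context,
             klass = ws_klass(from, to))
    }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), rel_pos = integer(),
                  from_base = character(), to_base = character(),
                  cpg_context = logical(), klass = character())
  }
  attr(out, "n_indels_skipped") <- n_indels
  out
}

#' Net-change and rate profiles of mapped de novo mutations
#'
#' The net series is (W->S minus S->W counts per offset) divided by the
#' number of genes analyzed, smoothed; the rate series divides per-type
#' counts by the per-offset count of the mutable base over the same gene
#' set. With `exclude_cpg_transitions`, CpG-context C->T and G->A records
#' are removed before any aggregation (both members of each strand pair are
#' named, so the filter is orientation-independent).
#'
#' @param mapped Output of [map_dnms()].
#' @param mutable_counts Per-offset base counts from the same gene windows
#'   (see [anchor_base_counts()]).
#' @param n_genes Number of genes analyzed.
#' @param window Sliding-window width (default 100).
#' @param exclude_cpg_transitions Drop CpG-context C->T / G->A records.
#' @param rate_types List of `c(from, to)` pairs for the rate series;
#'   defaults to the four transitions.
#' @return List with `net` (a `window_series`) and `rates` (tibble `offset`,
#'   `type`, `value`), plus `mapped` (the possibly filtered records).
#' @export
dnm_profiles <- function(mapped, mutable_counts, n_genes, window = 100,
                         exclude_cpg_transitions = FALSE,
                         rate_types = list(c("A", "G"), c("T", "C"),
                                           c("C", "T"), c("G", "A"))) {
  if (exclude_cpg_transitions) {
    mapped <- dplyr::filter(
      mapped,
      !(.data$cpg_context &
          ((.data$from_base == "C" & .data$to_base == "T") |
             (.data$from_base == "G" & .data$to_base == "A"))))
  }
  span <- max(abs(c(mutable_counts$offset,
                    mutable_counts$offset + 1L)))
  ev <- dplyr::rename(mapped, source_id = "gene_id")
  net <- net_gc_change_series(ev, span = span, window = window,
                              n_sources = n_genes)
  rates <- purrr::map(rate_types, function(ft) {
    s <- substitution_rate_series(ev, mutable_counts, ft[1], ft[2],
                                  window = window)
    tibble(offset = s$offset, type = paste0(ft[1], ">", ft[2]),
           value = s$value)
  }) |> dplyr::bind_rows()
  list(net = net, rates = rates, mapped = mapped)
}
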