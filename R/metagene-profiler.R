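#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; characters outside ACGT (e.g. N) are
#' excluded from both numerator and denominator. Returns `NA` if a sequence
#' has no ACGT bases.
#'
#' @param sequence Character vector of DNA strings (non-empty).
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction <- function(sequence) {
  if (any(!nzchar(sequence)) || length(sequence) == 0) {
    abort("empty sequence")
  }
  gc <- stringr::str_count(sequence, "[GCgc]")
  acgt <- stringr::str_count(sequence, "[ACGTacgt]")
  ifelse(acgt == 0, NA_real_, gc / acgt)
}

#' CpG dinucleotide density of a sequence
#'
#' Number of CG dinucleotides divided by `length - 1` (the number of
#' dinucleotide positions).
#'
#' @param sequence Character vector of DNA strings, each of length >= 2.
#' @return Numeric vector of CpG densities.
#' @export
cpg_density <- function(sequence) {
  n <- nchar(sequence)
  if (length(sequence) == 0 || any(n < 2)) {
    abort("sequences must have length >= 2")
  }
  stringr::str_count(toupper(sequence), "CG") / (n - 1)
}

#' Per-gene binned metagene values
#'
#' Computes a per-bin GC fraction for every gene under one of the three
#' binning schemes:
#'
#' * `"mrna20"` / `"orf40"`: each sequence is partitioned into 20 / 40
#'   equal-size bins (largest-remainder boundaries, all bins within 1 bp of
#'   each other). Input: tibble with `gene_id`, `sequence`, and optionally
#'   `weight` (isoform weight; per-gene values are isoform-weighted means).
#' * `"tsseib41"`: input is the output of [extract_eib_regions()]. Bins 1-20
#'   split the 2L upstream span, bin 21 is the single TSS base, bins 22-31
#'   split the first exon, bins 32-41 split the first L bp of intron 1. L
#'   must be >= 10 so every bin is non-empty (shorter genes are skipped).
#'
#' @param items Input tibble (see above).
#' @param scheme One of `"mrna20"`, `"tsseib41"`, `"orf40"`.
#' @return Tibble `gene_id`, `bin`, `value`, with skipped genes recorded in
#'   the `skipped` attribute.
#' @export
bin_gene_values <- function(items, scheme = c("mrna20", "tsseib41", "orf40")) {
  scheme <- match.arg(scheme)
  if (scheme == "tsseib41") return(bin_gene_values_tsseib(items))
  n_bins <- if (scheme == "mrna20") 20L else 40L
  if (!"weight" %in% names(items)) items$weight <- 1
  skipped <- items |>
    dplyr::filter(nchar(.data$sequence) < n_bins) |>
    dplyr::transmute(gene_id = .data$gene_id, reason = "sequence shorter than bin count")
  kept <- dplyr::filter(items, nchar(.data$sequence) >= n_bins)
  per_iso <- purrr::pmap(kept, function(gene_id, sequence, weight, ...) {
    b <- bin_boundaries(nchar(sequence), n_bins)
    vals <- gc_fraction(substring(sequence, b[-length(b)] + 1L, b[-1]))
    tibble(gene_id = gene_id, bin = seq_len(n_bins), value = vals,
           weight = weight)
  }) |> dplyr::bind_rows()
  out <- per_iso |>
    dplyr::group_by(.data$gene_id, .data$bin) |>
    dplyr::summarise(value = sum(.data$value * .data$weight) / sum(.data$weight),
                     .groups = "drop")
  attr(out, "skipped") <- skipped
  out
}

bin_gene_values_tsseib <- function(items) {
  skipped <- items |>
    dplyr::filter(.data$first_exon_length < 10L) |>
    dplyr::transmute(gene_id = .data$gene_id, reason = "first exon shorter than 10 bp")
  kept <- dplyr::filter(items, .data$first_exon_length >= 10L)
  out <- purrr::pmap(kept, function(gene_id, upstream, exon1, intron1_prefix,
                                    first_exon_length, ...) {
    up_b <- bin_boundaries(nchar(upstream), 20L)
    ex_b <- bin_boundaries(nchar(exon1), 10L)
    in_b <- bin_boundaries(nchar(intron1_prefix), 10L)
    vals <- c(
      gc_fraction(substring(upstream, up_b[-21] + 1L, up_b[-1])),
      gc_fraction(substr(exon1, 1L, 1L)),          # bin 21: the TSS base
      gc_fraction(substring(exon1, ex_b[-11] + 1L, ex_b[-1])),
      gc_fraction(substring(intron1_prefix, in_b[-11] + 1L, in_b[-1]))
    )
    tibble(gene_id = gene_id, bin = 1:41, value = vals)
  }) |> dplyr::bind_rows()
  attr(out, "skipped") <- skipped
  out
}

#' Binned metagene profile (mean over genes)
#'
#' Aggregates [bin_gene_values()] into the per-bin mean with contributing
#' gene counts. Isoform weighting happens within genes; the mean across genes
#' is unweighted.
#'
#' @inheritParams bin_gene_values
#' @return A `binned_profile` tibble: `bin`, `value`, `n_genes`; attribute
#'   `scheme`.
#' @export
bin_profile <- function(items, scheme = c("mrna20", "tsseib41", "orf40")) {
  scheme <- match.arg(scheme)
  per_gene <- bin_gene_values(items, scheme)
  out <- per_gene |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     n_genes = sum(!is.na(.data$value)), .groups = "drop")
  attr(out, "scheme") <- scheme
  attr(out, "skipped") <- attr(per_gene, "skipped")
  class(out) <- c("binned_profile", class(out))
  out
}

#' Per-position nucleotide and CpG profile around an anchor
#'
#' For a set of anchored regions (all sharing the same anchor semantics),
#' computes at every offset the fraction of A, C, G, T (over ACGT bases), the
#' overall GC fraction, and the CpG start fraction (a CpG is attributed to
#' the offset of its C). `coverage` counts the regions contributing an ACGT
#' base at that offset.
#'
#' @param regions Tibble with `sequence` and `anchor_offset` columns (e.g.
#'   from [extract_anchor_window()]).
#' @return A `positional_profile` tibble: `offset`, `a`, `c`, `g`, `t`, `gc`,
#'   `cpg`, `coverage`.
#' @export
positional_profile <- function(regions) {
  if (nrow(regions) == 0) abort("empty region set")
  per_region <- purrr::pmap(
    list(regions$sequence, regions$anchor_offset),
    function(sequence, anchor_offset) {
      ch <- seq_chars(toupper(sequence))
      n <- length(ch)
      is_cpg <- c(ch[-n] == "C" & ch[-1] == "G", FALSE)
      tibble(offset = seq_len(n) - 1L - anchor_offset, base = ch,
             cpg = is_cpg)
    }) |> dplyr::bind_rows()
  per_region |>
    dplyr::filter(.data$base %in% c("A", "C", "G", "T")) |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      a = mean(.data$base == "A"), c = mean(.data$base == "C"),
      g = mean(.data$base == "G"), t = mean(.data$base == "T"),
      gc = mean(.data$base %in% c("G", "C")),
      cpg = mean(.data$cpg),
      coverage = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$offset) |>
    structure(class = c("positional_profile", class(tibble())))
}

#' Per-offset base counts over anchored regions
#'
#' Counts how many regions carry each base at each offset; these are the
#' "mutable nucleotide" denominators for substitution and DNM rate series.
#'
#' @inheritParams positional_profile
#' @return Tibble `offset`, `A`, `C`, `G`, `T`.
#' @export
anchor_base_counts <- function(regions) {
  if (nrow(regions) == 0) abort("empty region set")
  out <- purrr::pmap(
    list(regions$sequence, regions$anchor_offset),
    function(sequence, anchor_offset) {
      ch <- seq_chars(toupper(sequence))
      tibble(offset = seq_along(ch) - 1L - anchor_offset, base = ch)
    }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$base %in% c("A", "C", "G", "T")) |>
    dplyr::count(.data$offset, .data$base) |>
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$offset)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(out)) out[[b]] <- 0L
  }
  out[, c("offset", "A", "C", "G", "T")]
}

#' @rdname sliding_mean
#' @param series Numeric vector of per-position values.
#' @export
sliding_window <- function(series, window = 100) sliding_mean(series, window)
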