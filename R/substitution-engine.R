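#' Infer lineage-assigned substitutions by outgroup parsimony
#'
#' Column rule (a = ingroup 1, b = ingroup 2, o = outgroup): columns with any
#' gap or N are discarded; `a == b` means no call; if `a != b` and `o == b`,
#' an event is called on ingroup 1 with ancestral `o` and derived `a`;
#' symmetrically for ingroup 2; columns where all three differ are ambiguous
#' and discarded. Positions are reported in each ingroup's own ungapped
#' coordinates relative to the anchor (sequences are assumed to be in
#' transcript orientation already). CpG context is evaluated on the inferred
#' ancestral ingroup sequence (the extant sequence with all called events
#' reverted), checking both CpG positions.
#'
#' @param alignment A `trio_alignment` (should have passed
#'   [identity_gate()]).
#' @param anchor_offset 0-based index of the anchor within each ungapped
#'   ingroup sequence.
#' @param source_id Identifier copied onto every event.
#' @return Tibble of events: `source_id`, `rel_pos`, `lineage`
#'   (`ingroup1`/`ingroup2`), `from_base`, `to_base`, `cpg_context`, `klass`
#'   (WS/SW/WW/SS).
#' @export
infer_substitutions <- function(alignment, anchor_offset,
                                source_id = "locus") {
  a <- seq_chars(alignment$gapped_in1)
  b <- seq_chars(alignment$gapped_in2)
  o <- seq_chars(alignment$gapped_out)
  bases <- c("A", "C", "G", "T")
  valid <- a %in% bases & b %in% bases & o %in% bases
  pos_a <- cumsum(a != "-") - 1L   # ungapped 0-based position per column
  pos_b <- cumsum(b != "-") - 1L

  call1 <- valid & a != b & o == b   # event on ingroup 1: o -> a
  call2 <- valid & a != b & o == a   # event on ingroup 2: o -> b

  ev1 <- tibble(
    source_id = source_id,
    lineage = "ingroup1",
    col = which(call1),
    pos = pos_a[call1],
    rel_pos = pos_a[call1] - anchor_offset,
    from_base = o[call1], to_base = a[call1]
  )
  ev2 <- tibble(
    source_id = source_id,
    lineage = "ingroup2",
    col = which(call2),
    pos = pos_b[call2],
    rel_pos = pos_b[call2] - anchor_offset,
    from_base = o[call2], to_base = b[call2]
  )

  # ancestral ingroup sequences: extant with called events reverted
  anc_cpg <- function(extant_chars, gapped, ev) {
    ungapped <- extant_chars[gapped != "-"]
    if (nrow(ev) > 0) ungapped[ev$pos + 1L] <- ev$from_base
    n <- length(ungapped)
    if (nrow(ev) == 0) return(logical(0))
    p <- ev$pos + 1L
    nxt <- ifelse(p < n, ungapped[pmin(p + 1L, n)], "")
    prv <- ifelse(p > 1L, ungapped[pmax(p - 1L, 1L)], "")
    (ev$from_base == "C" & nxt == "G") | (ev$from_base == "G" & prv == "C")
  }
  ev1$cpg_context <- anc_cpg(a, a, ev1)
  ev2$cpg_context <- anc_cpg(b, b, ev2)

  out <- dplyr::bind_rows(ev1, ev2)
  if (nrow(out) == 0) {
    return(tibble(source_id = character(), rel_pos = integer(),
                  lineage = character(), from_base = character(),
                  to_base = character(), cpg_context = logical(),
                  klass = character()))
  }
  out |>
    dplyr::mutate(klass = ws_klass(.data$from_base, .data$to_base)) |>
    dplyr::select("source_id", "rel_pos", "lineage", "from_base", "to_base",
                  "cpg_context", "klass") |>
    dplyr::arrange(.data$rel_pos)
}

#' Reconstruct the inferred ancestral ingroup window
#'
#' Reverts every called event of one lineage on that lineage's ungapped
#' sequence; the result feeds ancestral base-count denominators and GC4 site
#' classification.
#'
#' @param alignment A `trio_alignment`.
#' @param events Event tibble from [infer_substitutions()] for this
#'   alignment.
#' @param lineage `"ingroup1"` or `"ingroup2"`.
#' @param anchor_offset Anchor index used when the events were called.
#' @return The ancestral DNA string (ungapped ingroup coordinates).
#' @export
infer_ancestral_sequence <- function(alignment, events, lineage,
                                     anchor_offset = 0L) {
  gapped <- if (lineage == "ingroup1") alignment$gapped_in1
            else alignment$gapped_in2
  ch <- seq_chars(gapped)
  ungapped <- ch[ch != "-"]
  ev <- dplyr::filter(events, .data$lineage == !!lineage)
  if (nrow(ev) > 0) {
    ungapped[ev$rel_pos + anchor_offset + 1L] <- ev$from_base
  }
  paste(ungapped, collapse = "")
}

new_window_series <- function(offsets, values, n_sources, window) {
  structure(
    tibble(offset = offsets, value = values),
    n_sources = n_sources, window = window,
    class = c("window_series", class(tibble()))
  )
}

#' Net GC-change series around the anchor
#'
#' Per offset, (number of W->S events) minus (number of S->W events), divided
#' by the number of sources analyzed, then smoothed with a centered sliding
#' window. WW and SS events contribute zero.
#'
#' @param events Event tibble (any mix of lineages the caller wants pooled).
#' @param span Half-span in bp; the series covers offsets `-span` to
#'   `span - 1`.
#' @param window Sliding-window width (default 100).
#' @param n_sources Number of genes/regions analyzed (the normalizer).
#' @return A `window_series` tibble (`offset`, `value`) with attributes
#'   `n_sources` and `window`; attribute `raw` holds the pre-smoothing
#'   series.
#' @export
net_gc_change_series <- function(events, span, window = 100, n_sources) {
  offsets <- seq(-span, span - 1L)
  net <- numeric(length(offsets))
  if (nrow(events) > 0) {
    if (any(events$rel_pos < -span | events$rel_pos >= span)) {
      abort("events outside the requested span")
    }
    idx <- events$rel_pos + span + 1L
    delta <- ifelse(events$klass == "WS", 1,
                    ifelse(events$klass == "SW", -1, 0))
    net <- as.numeric(tapply(delta, factor(idx, levels = seq_along(offsets)),
                             sum, default = 0))
  }
  raw <- net / n_sources
  out <- new_window_series(offsets, sliding_mean(raw, window), n_sources,
                           window)
  attr(out, "raw") <- raw
  out
}

#' Per-offset substitution rate series
#'
#' Rate at an offset = events of the requested type divided by the count of
#' the ancestral `from_base` at that offset; offsets with a zero denominator
#' are undefined (`NA`) and excluded from smoothing rather than set to zero.
#'
#' @param events Event tibble.
#' @param base_counts Per-offset ancestral base counts (tibble `offset`,
#'   `A`, `C`, `G`, `T`), computed from the same gene set (e.g. with
#'   [anchor_base_counts()] on inferred ancestral windows).
#' @param from_base,to_base The substitution type, e.g. `"A"` to `"G"`.
#' @param window Sliding-window width.
#' @return A `window_series` tibble; attribute `raw` is pre-smoothing.
#' @export
substitution_rate_series <- function(events, base_counts, from_base, to_base,
                                     window = 100) {
  ev <- dplyr::filter(events, .data$from_base == !!from_base,
                      .data$to_base == !!to_base)
  if (nrow(ev) > 0 &&
      (min(ev$rel_pos) < min(base_counts$offset) ||
       max(ev$rel_pos) > max(base_counts$offset))) {
    abort("events fall outside the base-count offsets; gene sets mismatch")
  }
  offsets <- base_counts$offset
  counts <- as.numeric(tapply(rep(1, nrow(ev)),
                              factor(ev$rel_pos, levels = offsets),
                              sum, default = 0))
  if (nrow(ev) == 0) counts <- numeric(length(offsets))
  denom <- base_counts[[from_base]]
  raw <- ifelse(denom > 0, counts / denom, NA_real_)
  out <- new_window_series(offsets, sliding_mean(raw, window),
                           n_sources = NA_integer_, window = window)
  attr(out, "raw") <- raw
  out
}

FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")

#' Third positions of fourfold-degenerate codons in an ORF
#'
#' The ORF must begin with ATG and have length divisible by 3. Returns the
#' 0-based positions of third codon bases whose first two bases define a
#' fourfold-degenerate family (Ala, Gly, Pro, Thr, Val, Leu-CTN, Ser-TCN,
#' Arg-CGN), i.e. sites where any third base is synonymous.
#'
#' @param orf DNA string.
#' @return Integer vector of 0-based GC4 site positions.
#' @export
find_gc4_sites <- function(orf) {
  orf <- toupper(orf)
  if (substr(orf, 1, 3) != "ATG") abort("ORF must start with ATG")
  if (nchar(orf) %% 3 != 0) abort("ORF length must be divisible by 3")
  starts <- seq(1, nchar(orf), by = 3)
  prefixes <- substring(orf, starts, starts + 1L)
  which(prefixes %in% FOURFOLD_PREFIXES) * 3L - 1L
}

#' ORF-binned net GC change
#'
#' Maps events in spliced-ORF coordinates onto `n_bins` length-normalized
#' bins and averages the per-gene net GC change (W->S minus S->W counts) per
#' bin over all genes, including genes with zero events. With `gc4_only`,
#' events are first restricted to fourfold-degenerate third positions of the
#' inferred ancestral ORF (so a substitution cannot reclassify its own
#' site).
#'
#' @param events Tibble `source_id`, `pos` (0-based spliced ORF coordinate),
#'   `klass`.
#' @param orfs Tibble `source_id`, `orf_length`, and (when `gc4_only`)
#'   `ancestral_orf`.
#' @param n_bins Number of bins (default 40).
#' @param gc4_only Restrict to GC4 sites.
#' @return A `binned_profile` tibble (`bin`, `value`, `n_genes`); values are
#'   mean net counts per gene, not fractions.
#' @export
orf_binned_net_gc <- function(events, orfs, n_bins = 40L, gc4_only = FALSE) {
  ev <- dplyr::inner_join(events, orfs, by = "source_id")
  if (gc4_only && nrow(ev) > 0) {
    keep <- purrr::map_lgl(seq_len(nrow(ev)), function(i) {
      ev$pos[i] %in% find_gc4_sites(ev$ancestral_orf[i])
    })
    ev <- ev[keep, ]
  }
  per_gene <- matrix(0, nrow = nrow(orfs), ncol = n_bins,
                     dimnames = list(orfs$source_id, NULL))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      b <- bin_boundaries(ev$orf_length[i], n_bins)
      bin <- findInterval(ev$pos[i], b, rightmost.closed = TRUE)
      bin <- min(max(bin, 1L), n_bins)
      delta <- switch(ev$klass[i], WS = 1, SW = -1, 0)
      per_gene[ev$source_id[i], bin] <- per_gene[ev$source_id[i], bin] + delta
    }
  }
  out <- tibble(bin = seq_len(n_bins), value = colMeans(per_gene),
                n_genes = nrow(orfs))
  attr(out, "scheme") <- "orf40"
  class(out) <- c("binned_profile", class(out))
  out
}

#' Spliced-ORF intervals of each coding exon
#'
#' For every gene, maps the CDS onto spliced-ORF coordinates and reports
#' which half-open ORF interval each coding exon occupies (exon indices in
#' transcript order).
#'
#' @param genes Gene model tibble with `exons`, `cds_start`, `cds_end`.
#' @return Tibble `source_id`, `exon_index`, `orf_start`, `orf_end`,
#'   `n_coding_exons`.
#' @export
orf_exon_map <- function(genes) {
  purrr::pmap(genes, function(gene_id, strand, exons, cds_start, cds_end,
                              ...) {
    idx <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
    cum <- 0L
    rows <- list()
    k <- 0L
    for (j in idx) {
      s <- max(exons$start[j], cds_start)
      e <- min(exons$end[j], cds_end)
      if (e > s) {
        k <- k + 1L
        rows[[k]] <- tibble(source_id = gene_id, exon_index = k,
                            orf_start = cum, orf_end = cum + (e - s))
        cum <- cum + (e - s)
      }
    }
    if (k == 0) return(NULL)
    dplyr::bind_rows(rows) |> dplyr::mutate(n_coding_exons = k)
  }) |> dplyr::bind_rows()
}

#' Count W->S / S->W events confined to one coding exon
#'
#' Only genes with at least 4 coding exons are analyzed (others are excluded
#' with a reason in the `skipped` attribute). Events are counted within the
#' spliced-ORF interval of the chosen exon.
#'
#' @param events Tibble `source_id`, `pos` (spliced ORF coordinate),
#'   `klass`.
#' @param exon_map Output of [orf_exon_map()].
#' @param exon_index Which coding exon to count (1 or 4 in the standard
#'   contrast).
#' @return Tibble `source_id`, `ws`, `sw`.
#' @export
count_events_by_exon <- function(events, exon_map, exon_index) {
  eligible <- exon_map |>
    dplyr::filter(.data$n_coding_exons >= 4L)
  skipped <- exon_map |>
    dplyr::filter(.data$n_coding_exons < 4L) |>
    dplyr::distinct(.data$source_id) |>
    dplyr::mutate(reason = "fewer than 4 coding exons")
  tgt <- dplyr::filter(eligible, .data$exon_index == !!exon_index)
  out <- tgt |>
    dplyr::left_join(events, by = "source_id") |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      ws = sum(!is.na(.data$pos) & .data$pos >= .data$orf_start &
                 .data$pos < .data$orf_end & .data$klass == "WS"),
      sw = sum(!is.na(.data$pos) & .data$pos >= .data$orf_start &
                 .data$pos < .data$orf_end & .data$klass == "SW"),
      .groups = "drop"
    )
  attr(out, "skipped") <- skipped
  out
}

#' Run the trio substitution pipeline over simulated or loaded loci
#'
#' Aligns each trio (or, when the loci are known to be indel-free, stacks
#' them directly), applies the identity gate, and pools inferred events.
#'
#' @param loci List of `trio_locus` objects (or lists with `in1`, `in2`,
#'   `out`, `anchor`).
#' @param scoring A [scoring_scheme()].
#' @param align Run [align_trio()] (default) or stack equal-length sequences
#'   as a gapless alignment.
#' @param min_identity Identity gate threshold.
#' @param band Optional alignment band half-width (see
#'   [needleman_wunsch()]); 0 for the full matrix.
#' @return List: `events` (pooled tibble), `n_sources` (loci passing the
#'   gate), `alignments` (per-locus `trio_alignment`s), `gate` (logical).
#' @export
call_trio_substitutions <- function(loci, scoring = scoring_scheme(),
                                    align = TRUE, min_identity = 0.60,
                                    band = 0L) {
  alns <- purrr::map(loci, function(l) {
    if (align) {
      align_trio(l$in1, l$in2, l$out, scoring, band = band)
    } else {
      stack_trio_alignment(l$in1, l$in2, l$out)
    }
  })
  gate <- purrr::map_lgl(alns, identity_gate, threshold = min_identity)
  names <- purrr::imap_chr(loci, function(l, i) sprintf("locus%04d", i))
  events <- purrr::pmap(list(alns, loci, names, gate),
                        function(a, l, nm, ok) {
    if (!ok) return(NULL)
    infer_substitutions(a, anchor_offset = l$anchor, source_id = nm)
  }) |> dplyr::bind_rows()
  list(events = events, n_sources = sum(gate), alignments = alns,
       gate = gate)
}

#' Treat three equal-length sequences as an (ungapped) alignment
#'
#' @param seq_in1,seq_in2,seq_out Equal-length DNA strings.
#' @return A `trio_alignment`.
#' @export
stack_trio_alignment <- function(seq_in1, seq_in2, seq_out) {
  if (length(unique(nchar(c(seq_in1, seq_in2, seq_out)))) != 1) {
    abort("sequences must have equal length to stack without alignment")
  }
  ident <- function(x, y) {
    cx <- seq_chars(x); cy <- seq_chars(y)
    mean(cx == cy & cx %in% c("A", "C", "G", "T"))
  }
  structure(
    list(gapped_in1 = toupper(seq_in1), gapped_in2 = toupper(seq_in2),
         gapped_out = toupper(seq_out),
         pairwise_identities = c(
           in1_in2 = ident(toupper(seq_in1), toupper(seq_in2)),
           in1_out = ident(toupper(seq_in1), toupper(seq_out)),
           in2_out = ident(toupper(seq_in2), toupper(seq_out))),
         columns = nchar(seq_in1), score = NA_real_),
    class = "trio_alignment"
  )
}

#' Audit inferred substitutions against a simulator truth table
#'
#' Classifies every locus site as single-hit (exactly one simulated event
#' across all three lineages) or multi-hit, then checks that inference is
#' perfect at single-hit sites: every ingroup truth event is recovered
#' (position, lineage, ancestral and derived base) and no false event is
#' called there. False calls at multi-hit sites are counted separately —
#' they are the expected failure mode of parsimony, not inference bugs.
#'
#' When `alignments` are supplied, loci whose produced alignment contains
#' gap columns are set aside (`n_gapped_loci`) rather than audited: the
#' per-column inference rule discards gap columns by contract, so truth
#' events hidden by an alignment artifact (e.g. a cluster of adjacent
#' substitutions that locally favors compensating gaps) are not callable.
#' They are reported, not silently dropped.
#'
#' @param loci List of `trio_locus` objects (with truth tables), in the
#'   order used by [call_trio_substitutions()].
#' @param events Pooled inferred event tibble (source ids
#'   `locus0001`, ...).
#' @param alignments Optional list of `trio_alignment`s (same order as
#'   `loci`), used to set aside gapped loci.
#' @return List of counts: `n_truth_single`, `recovered_single`,
#'   `missed_at_single_hit`, `false_at_single_hit`, `false_at_multi_hit`,
#'   `n_gapped_loci`, `n_truth_in_gapped`, `n_inferred`.
#' @export
audit_inference <- function(loci, events, alignments = NULL) {
  n_truth_single <- 0L
  recovered <- 0L
  missed <- 0L
  false_single <- 0L
  false_multi <- 0L
  n_gapped <- 0L
  n_truth_gapped <- 0L
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    id <- sprintf("locus%04d", i)
    truth <- l$truth
    if (!is.null(alignments)) {
      a <- alignments[[i]]
      if (grepl("-", paste0(a$gapped_in1, a$gapped_in2, a$gapped_out),
                fixed = TRUE)) {
        n_gapped <- n_gapped + 1L
        n_truth_gapped <- n_truth_gapped +
          sum(truth$lineage != "outgroup")
        next
      }
    }
    hit_counts <- table(truth$site)
    single_sites <- as.integer(names(hit_counts)[hit_counts == 1])
    multi_sites <- as.integer(names(hit_counts)[hit_counts > 1])
    tin <- dplyr::filter(truth, .data$lineage != "outgroup")
    tin_single <- dplyr::filter(tin, .data$site %in% single_sites)
    n_truth_single <- n_truth_single + nrow(tin_single)

    ev <- dplyr::filter(events, .data$source_id == id) |>
      dplyr::mutate(site = .data$rel_pos + l$anchor)
    truth_keys <- paste(tin_single$site, tin_single$lineage,
                        tin_single$from_base, tin_single$to_base)
    ev_single <- dplyr::filter(ev, .data$site %in% single_sites)
    ev_keys <- paste(ev_single$site, ev_single$lineage,
                     ev_single$from_base, ev_single$to_base)
    recovered <- recovered + sum(truth_keys %in% ev_keys)
    missed <- missed + sum(!truth_keys %in% ev_keys)
    false_single <- false_single + sum(!ev_keys %in% truth_keys)
    # any other call sits at a multi-hit site (or disagrees with the truth
    # there) — the expected parsimony failure mode
    ev_rest <- dplyr::filter(ev, !.data$site %in% single_sites)
    rest_keys <- paste(ev_rest$site, ev_rest$lineage, ev_rest$from_base,
                       ev_rest$to_base)
    tin_keys <- paste(tin$site, tin$lineage, tin$from_base, tin$to_base)
    false_multi <- false_multi + sum(!rest_keys %in% tin_keys)
    stopifnot(all(ev_rest$site %in% multi_sites |
                    !rest_keys %in% tin_keys))
  }
  list(n_truth_single = n_truth_single, recovered_single = recovered,
       missed_at_single_hit = missed, false_at_single_hit = false_single,
       false_at_multi_hit = false_multi,
       n_gapped_loci = n_gapped, n_truth_in_gapped = n_truth_gapped,
       n_inferred = nrow(events))
}
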