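#' Parameterize the nucleotide mutation process
#'
#' The process is AT-biased (weak/strong asymmetric), CpG-hypermutable, and
#' optionally carries a GC-biased gene conversion (gBGC) term near an anchor.
#' Relative substitution weights give each transition `ts_tv_ratio` times the
#' weight of each transversion, normalized so an unbiased site mutates at
#' `base_rate` per branch-length unit. On top of that:
#'
#' * every A/T to G/C (weak-to-strong, W->S) rate is multiplied by `ws_bias`
#'   (values < 1 encode the genome-wide mutational drift toward AT);
#' * C->T and G->A rates are multiplied by `cpg_multiplier` when the site sits
#'   in a CpG on the current sequence, except within `hypomethyl_window` bp of
#'   the anchor where the multiplier is reset to 1 (promoter hypomethylation);
#' * within `gbgc_window` bp of the anchor, W->S rates are multiplied by
#'   `(1 + gbgc_strength)` and S->W rates by `(1 - gbgc_strength)`. The
#'   default strength 0.4 is the value B solving (1+B)/(1-B) = 70/30, i.e. a
#'   70% repair bias in favor of G and C; the window defaults to 0 so the
#'   conversion bias is off unless requested.
#'
#' @param base_rate Expected substitutions per unbiased site per branch-length
#'   unit.
#' @param ts_tv_ratio Transition:transversion rate ratio.
#' @param ws_bias Multiplier on A/T -> G/C rates.
#' @param cpg_multiplier Extra factor on CpG transitions (C->T, G->A).
#' @param gbgc_strength B in \[0, 1): conversion bias toward G/C near the
#'   anchor.
#' @param gbgc_window Half-width in bp of the gBGC window around the anchor.
#' @param hypomethyl_window Half-width in bp of the hypomethylated window
#'   around the anchor (CpG multiplier suppressed there).
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(base_rate = 1, ts_tv_ratio = 2, ws_bias = 0.5,
                           cpg_multiplier = 10, gbgc_strength = 0.4,
                           gbgc_window = 0, hypomethyl_window = 0) {
  if (any(c(base_rate, ts_tv_ratio, ws_bias, cpg_multiplier) < 0)) {
    abort("all rates must be >= 0")
  }
  if (gbgc_strength < 0 || gbgc_strength >= 1) {
    abort("`gbgc_strength` must be in [0, 1)")
  }
  if (gbgc_window < 0 || hypomethyl_window < 0) abort("windows must be >= 0")
  structure(
    list(base_rate = base_rate, ts_tv_ratio = ts_tv_ratio, ws_bias = ws_bias,
         cpg_multiplier = cpg_multiplier, gbgc_strength = gbgc_strength,
         gbgc_window = as.integer(gbgc_window),
         hypomethyl_window = as.integer(hypomethyl_window)),
    class = "mutation_model"
  )
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
STRONG <- c("G", "C")

# Per-site rates to each of the three target bases, given the current
# sequence context. Returns a 3-column matrix (ts, tv1, tv2) plus the target
# base matrix; used both for Poisson totals and for sampling targets.
site_target_rates <- function(chars, model, anchor = NULL,
                              hypo_positions = NULL) {
  n <- length(chars)
  kappa <- model$ts_tv_ratio
  w_ts <- model$base_rate * kappa / (kappa + 2)
  w_tv <- model$base_rate / (kappa + 2)

  # targets: column 1 transition, columns 2-3 the two transversions
  t_ts <- TRANSITION[chars]
  t_tv1 <- ifelse(chars %in% c("A", "G"), "C", "A")
  t_tv2 <- ifelse(chars %in% c("A", "G"), "T", "G")
  targets <- cbind(t_ts, t_tv1, t_tv2)

  rates <- cbind(rep(w_ts, n), rep(w_tv, n), rep(w_tv, n))

  from_w <- chars %in% c("A", "T")
  to_s <- matrix(targets %in% STRONG, nrow = n)
  ws <- from_w & to_s      # weak -> strong cells
  sw <- !from_w & !to_s    # strong -> weak cells
  rates[ws] <- rates[ws] * model$ws_bias

  # positional windows around the anchor (0-based site index)
  pos <- seq_len(n) - 1L
  if (!is.null(anchor) && model$gbgc_strength > 0 && model$gbgc_window > 0) {
    in_gbgc <- abs(pos - anchor) <= model$gbgc_window
    rates[ws & in_gbgc] <- rates[ws & in_gbgc] * (1 + model$gbgc_strength)
    rates[sw & in_gbgc] <- rates[sw & in_gbgc] * (1 - model$gbgc_strength)
  }

  # CpG transitions: C->T with next G, G->A with previous C
  if (model$cpg_multiplier != 1) {
    nxt <- c(chars[-1], "")
    prv <- c("", chars[-n])
    cpg_site <- (chars == "C" & nxt == "G") | (chars == "G" & prv == "C")
    if (!is.null(anchor) && model$hypomethyl_window > 0) {
      cpg_site <- cpg_site & abs(pos - anchor) > model$hypomethyl_window
    }
    if (!is.null(hypo_positions) && length(hypo_positions) > 0) {
      cpg_site[hypo_positions + 1L] <- FALSE
    }
    rates[cpg_site, 1] <- rates[cpg_site, 1] * model$cpg_multiplier
  }
  list(targets = targets, rates = rates, total = rowSums(rates))
}

#' Evolve a sequence along one branch
#'
#' Per site, the number of hits is Poisson with mean `total site rate x
#' branch_length` (rates evaluated on the ancestor); hits are then applied
#' sequentially, re-evaluating the current base and CpG context before each
#' event, so multiple hits and context changes compose correctly. The
#' returned truth table replays exactly to the derived sequence.
#'
#' @param ancestor DNA string.
#' @param model A [mutation_model()].
#' @param branch_length Branch length (>= 0) in the model's rate units.
#' @param anchor 0-based anchor position for the gBGC / hypomethylation
#'   windows, or `NULL`.
#' @param seed Integer seed.
#' @return List with `sequence` (derived DNA string) and `truth`, a tibble of
#'   events: `site` (0-based), `from_base`, `to_base`, `order_index`.
#' @export
evolve_sequence <- function(ancestor, model, branch_length, anchor = NULL,
                            seed = 1L) {
  if (branch_length < 0) abort("`branch_length` must be >= 0")
  chars <- seq_chars(ancestor)
  n <- length(chars)
  if (branch_length == 0) {
    return(list(sequence = ancestor, truth = empty_truth()))
  }
  with_seed(seed, {
    sr <- site_target_rates(chars, model, anchor)
    hits <- rpois(n, sr$total * branch_length)
    mut_sites <- which(hits > 0)
    events <- vector("list", sum(hits))
    k <- 0L
    for (i in mut_sites) {
      for (h in seq_len(hits[i])) {
        win <- max(1L, i - 1L):min(n, i + 1L)
        local <- site_target_rates(chars[win], model,
                                   anchor = if (is.null(anchor)) NULL
                                            else anchor - (win[1] - 1L))
        j <- which(win == i)
        r <- local$rates[j, ]
        if (sum(r) <= 0) next
        to <- sample(local$targets[j, ], 1L, prob = r)
        k <- k + 1L
        events[[k]] <- tibble(site = i - 1L, from_base = chars[i],
                              to_base = to, order_index = k)
        chars[i] <- to
      }
    }
    truth <- if (k > 0) dplyr::bind_rows(events[seq_len(k)]) else empty_truth()
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

empty_truth <- function() {
  tibble(site = integer(), from_base = character(), to_base = character(),
         order_index = integer())
}

#' Replay a truth table over an ancestor
#'
#' Applies events in `order_index` order; used to verify simulator
#' consistency.
#'
#' @param ancestor DNA string.
#' @param truth Truth tibble from [evolve_sequence()].
#' @return The derived DNA string.
#' @export
replay_truth <- function(ancestor, truth) {
  chars <- seq_chars(ancestor)
  truth <- dplyr::arrange(truth, .data$order_index)
  for (k in seq_len(nrow(truth))) {
    i <- truth$site[k] + 1L
    if (chars[i] != truth$from_base[k]) {
      abort(sprintf("truth event %d expects %s at site %d but found %s",
                    k, truth$from_base[k], truth$site[k], chars[i]))
    }
    chars[i] <- truth$to_base[k]
  }
  paste(chars, collapse = "")
}

#' Simulate a homologous trio from a common ancestor
#'
#' Star tree: the two ingroups and the outgroup each evolve independently
#' from the same ancestor (no indels, so all four sequences stay the same
#' length). The union truth table carries lineage labels; it is the oracle
#' against which outgroup-parsimony inference is audited.
#'
#' @param ancestor DNA string.
#' @param model A [mutation_model()].
#' @param branch_lengths Numeric vector `c(t_in1, t_in2, t_out)`, all >= 0.
#' @param anchor 0-based anchor position (e.g. a TSS at the window center).
#' @param seed Integer seed.
#' @return A `trio_locus` list: `ancestor`, `in1`, `in2`, `out`, `anchor`,
#'   `truth` (tibble with `lineage` in ingroup1/ingroup2/outgroup).
#' @export
simulate_trio <- function(ancestor, model, branch_lengths, anchor = NULL,
                          seed = 1L) {
  if (length(branch_lengths) != 3 || any(branch_lengths < 0)) {
    abort("`branch_lengths` must be three values >= 0")
  }
  lineages <- c("ingroup1", "ingroup2", "outgroup")
  res <- purrr::map2(branch_lengths, seq_along(lineages), function(t, k) {
    evolve_sequence(ancestor, model, t, anchor = anchor,
                    seed = seed * 7 + k)
  })
  truth <- purrr::map2(res, lineages, function(r, lin) {
    dplyr::mutate(r$truth, lineage = lin, .after = "site")
  }) |> dplyr::bind_rows()
  structure(
    list(ancestor = ancestor, in1 = res[[1]]$sequence,
         in2 = res[[2]]$sequence, out = res[[3]]$sequence,
         anchor = anchor, truth = truth),
    class = "trio_locus"
  )
}

#' @export
print.trio_locus <- function(x, ...) {
  cat(sprintf("<trio_locus> %d bp, anchor %s, %d truth events\n",
              nchar(x$ancestor),
              if (is.null(x$anchor)) "none" else x$anchor,
              nrow(x$truth)))
  invisible(x)
}

#' Simulate a set of trio loci over independent ancestors
#'
#' Each ancestor is drawn from a [genome_spec()]-style background with an
#' optional GC peak at the anchor (the window midpoint), then evolved as in
#' [simulate_trio()].
#'
#' @param n_loci Number of loci.
#' @param locus_length Length of each locus in bp.
#' @param model A [mutation_model()].
#' @param branch_lengths `c(t_in1, t_in2, t_out)`.
#' @param background_gc Ancestor background GC.
#' @param peak Optional [gc_peak_spec()] planted at the anchor.
#' @param seed Integer seed.
#' @return List of `trio_locus` objects; each has `anchor = locus_length/2`.
#' @export
simulate_trio_set <- function(n_loci, locus_length, model, branch_lengths,
                              background_gc = 0.41, peak = NULL, seed = 1L) {
  anchor <- as.integer(locus_length / 2)
  peaks <- if (is.null(peak)) NULL else
    tibble(position = anchor, amplitude = peak$amplitude, sigma = peak$sigma,
           center_offset = peak$center_offset)
  purrr::map(seq_len(n_loci), function(i) {
    spec <- genome_spec(sprintf("locus%04d", i), locus_length,
                        background_gc = background_gc,
                        seed = (seed + 131 * i) %% 2147483647)
    anc <- simulate_genome_sequence(spec, peaks)
    simulate_trio(anc, model, branch_lengths, anchor = anchor,
                  seed = seed + 131 * i + 1)
  })
}

#' Sample synthetic de novo mutations from a genome
#'
#' Sites are sampled proportionally to their per-site mutation rate under
#' `model`, with the CpG multiplier suppressed within `model$hypomethyl_window`
#' bp of any TSS in `genes`; given a site, the alternate base is sampled
#' proportionally to the per-target rates. Mutations are independent (sites
#' may repeat), emulating a population-scale trio-sequencing DNM catalog.
#'
#' @param sequence Named character vector of length 1 (the chromosome).
#' @param genes Gene model tibble (for TSS hypomethylation windows); may have
#'   zero rows.
#' @param model A [mutation_model()].
#' @param n_mutations Number of DNM records to draw (>= 0).
#' @param seed Integer seed.
#' @return Tibble `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
simulate_dnms <- function(sequence, genes, model, n_mutations, seed = 1L) {
  if (n_mutations < 0) abort("`n_mutations` must be >= 0")
  chrom <- names(sequence) %||% "chrS"
  if (n_mutations == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  chars <- seq_chars(unname(sequence[1]))
  hypo <- integer(0)
  if (nrow(genes) > 0 && model$hypomethyl_window > 0) {
    hypo <- unique(unlist(lapply(genes$tss, function(t) {
      lo <- max(0L, t - model$hypomethyl_window)
      hi <- min(length(chars) - 1L, t + model$hypomethyl_window)
      lo:hi
    })))
  }
  sr <- site_target_rates(chars, model, anchor = NULL, hypo_positions = hypo)
  with_seed(seed, {
    sites <- sample.int(length(chars), n_mutations, replace = TRUE,
                        prob = sr$total)
    alt <- vapply(sites, function(i) {
      sample(sr$targets[i, ], 1L, prob = sr$rates[i, ])
    }, character(1))
    tibble(chrom = chrom, pos = sites, ref = chars[sites], alt = alt) |>
      dplyr::arrange(.data$pos)
  })
}
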