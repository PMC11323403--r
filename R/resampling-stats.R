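#' Per-gene difference between two profile bins
#'
#' The start-vs-middle contrast: for each gene, `value(bin_i) -
#' value(bin_j)`. Genes missing either bin are excluded (recorded in the
#' `skipped` attribute); the mean delta is attached as `mean_delta`.
#'
#' @param gene_bins Long tibble `gene_id`, `bin`, `value` (see
#'   [bin_gene_values()]).
#' @param bin_i,bin_j Bin indices to contrast (defaults 1 and 11, the start
#'   and middle of a 20-bin mRNA profile).
#' @return Tibble `gene_id`, `delta`; attributes `mean_delta`, `skipped`.
#' @export
bin_delta <- function(gene_bins, bin_i = 1L, bin_j = 11L) {
  wide <- gene_bins |>
    dplyr::filter(.data$bin %in% c(bin_i, bin_j)) |>
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "bin",
                       values_from = "value", names_prefix = "b")
  ci <- paste0("b", bin_i); cj <- paste0("b", bin_j)
  for (cc in c(ci, cj)) if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  ok <- !is.na(wide[[ci]]) & !is.na(wide[[cj]])
  skipped <- tibble(gene_id = wide$gene_id[!ok], reason = "missing bin")
  out <- tibble(gene_id = wide$gene_id[ok],
                delta = wide[[ci]][ok] - wide[[cj]][ok])
  attr(out, "mean_delta") <- mean(out$delta)
  attr(out, "skipped") <- skipped
  out
}

#' Wilcoxon signed-rank test for paired values
#'
#' Differences of zero are dropped; ties are mid-ranked. For up to 25
#' effective pairs the null distribution of the signed-rank sum W is exact
#' (sign-flip enumeration via convolution over the realized rank multiset,
#' so mid-ranks are handled exactly); above that, a normal approximation
#' with tie correction and continuity correction is used. Two-sided by
#' default.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest `n_effective` for which the exact null is used.
#' @return A `wilcoxon_result`: `statistic` (W, sum of positive ranks),
#'   `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("`x` and `y` must be equal-length, non-empty")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_wilcoxon(0, 1, 0L, "degenerate (all differences zero)"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: W is a sum over the realized ranks, each included with
    # probability 1/2; convolve on doubled ranks to stay integer
    r2 <- as.integer(round(2 * r))
    total2 <- sum(r2)
    counts <- c(1, numeric(total2))  # counts[s+1] = #assignments with 2W = s
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(total2 + 1 - rr)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(probs[(w2 + 1):(total2 + 1)])
    p_le <- sum(probs[1:(w2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    return(new_wilcoxon(W, p, n, "exact sign-flip enumeration"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_wilcoxon(W, p, n, "normal approximation with tie correction")
}

new_wilcoxon <- function(W, p, n_eff, method) {
  structure(list(statistic = W, p_value = p, n_effective = n_eff,
                 method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n_eff = %d, p = %.4g (%s)\n",
              x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}

#' @export
tidy.wilcoxon_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n.effective = x$n_effective, method = x$method)
}

#' @export
glance.wilcoxon_result <- function(x, ...) tidy(x)

#' Label-shuffling permutation test for a difference of group means
#'
#' The observed statistic is `mean(group_a) - mean(group_b)`. The pooled
#' values are reshuffled into two groups of the original sizes `n_perm`
#' times (or exhaustively over all distinct assignments when `exhaustive`),
#' giving the null distribution of deltas. Two p-values are reported:
#'
#' * `p_empirical`: `(1 + #{|null| >= |observed|}) / (n_perm + 1)`
#'   (distribution-free; exact fraction, without the +1 correction, in
#'   exhaustive mode);
#' * `p_gaussian`: tail area beyond the observed delta under a normal fitted
#'   to the null deltas — doubled and capped at 1 for the two-sided report
#'   (the tail on the observed side is used, so relabeling the groups leaves
#'   the two-sided p unchanged).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (Monte-Carlo mode).
#' @param exhaustive Enumerate all distinct assignments (feasible for small
#'   groups only; capped at 2e5 combinations).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return A `perm_test` object.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 1000L, seed = 1L,
                             exhaustive = FALSE,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  na <- length(group_a)
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  observed <- mean(group_a) - mean(group_b)

  if (exhaustive) {
    n_comb <- choose(n, na)
    if (n_comb > 2e5) {
      abort("too many assignments for exhaustive mode; use Monte Carlo")
    }
    idx <- utils::combn(n, na)
    null_deltas <- apply(idx, 2, function(i) {
      mean(pooled[i]) - mean(pooled[-i])
    })
    p_emp <- switch(alternative,
      two.sided = mean(abs(null_deltas) >= abs(observed) - 1e-12),
      greater = mean(null_deltas >= observed - 1e-12),
      less = mean(null_deltas <= observed + 1e-12))
  } else {
    # draw the smaller group's indices from the sorted pool so that swapping
    # the group labels (same seed) negates every null delta and leaves the
    # two-sided p intact
    k_small <- min(na, n - na)
    a_is_small <- na <= n - na
    pool_sorted <- sort(pooled)
    null_deltas <- with_seed(seed, {
      vapply(seq_len(n_perm), function(k) {
        i <- sample.int(n, k_small)
        d <- mean(pool_sorted[i]) - mean(pool_sorted[-i])
        if (a_is_small) d else -d
      }, numeric(1))
    })
    p_emp <- switch(alternative,
      two.sided = (1 + sum(abs(null_deltas) >= abs(observed))) / (n_perm + 1),
      greater = (1 + sum(null_deltas >= observed)) / (n_perm + 1),
      less = (1 + sum(null_deltas <= observed)) / (n_perm + 1))
  }

  mu <- mean(null_deltas)
  s <- sd(null_deltas)
  if (is.na(s) || s == 0) {
    p_gauss <- if (abs(observed - mu) < .Machine$double.eps^0.5) 1
               else 1 / (length(null_deltas) + 1)
  } else {
    upper <- 1 - pnorm(observed, mean = mu, sd = s)
    lower <- pnorm(observed, mean = mu, sd = s)
    p_gauss <- switch(alternative,
      two.sided = min(1, 2 * min(upper, lower)),
      greater = upper,
      less = lower)
  }

  structure(
    list(observed_delta = observed, null_deltas = null_deltas,
         p_gaussian = p_gauss, p_empirical = p_emp,
         n_perm = length(null_deltas), seed = seed,
         alternative = alternative, exhaustive = exhaustive),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s%s): observed delta = %.4g\n  p_empirical = %.4g, p_gaussian = %.4g (%d permutations)\n",
    x$alternative, if (x$exhaustive) ", exhaustive" else "",
    x$observed_delta, x$p_empirical, x$p_gaussian, x$n_perm))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed.delta = x$observed_delta, p.empirical = x$p_empirical,
         p.gaussian = x$p_gaussian, n.perm = x$n_perm,
         alternative = x$alternative, exhaustive = x$exhaustive)
}

#' @export
glance.perm_test <- function(x, ...) tidy(x)
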