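# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (recursion, enumeration, per-site loops)
# rather than calling the package internals they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Optimal global alignment score by memoized recursion over the three
# alignment moves (independent of the package's iterative DP).
brute_nw_score <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  n <- length(c1); m <- length(c2)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    r <- if (i == 0 && j == 0) 0
    else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (c1[i] == c2[j]) match else mismatch
        best <- max(best, rec(i - 1, j - 1) + s)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) + gap)
      if (j > 0) best <- max(best, rec(i, j - 1) + gap)
      best
    }
    memo[i + 1, j + 1] <<- r
    r
  }
  rec(n, m)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  p_ge <- mean(W_all >= W - 1e-9)
  p_le <- mean(W_all <= W + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# Per-site total mutation rate (and the CpG-transition component), computed
# by a direct per-site loop over the model definition.
oracle_site_rates <- function(chars, model, anchor = NULL) {
  n <- length(chars)
  kappa <- model$ts_tv_ratio
  trans <- c(A = "G", G = "A", C = "T", T = "C")
  strong <- c("G", "C")
  total <- numeric(n)
  cpg_ts <- numeric(n)
  for (i in seq_len(n)) {
    b <- chars[i]
    if (!b %in% c("A", "C", "G", "T")) next
    for (t in setdiff(c("A", "C", "G", "T"), b)) {
      w <- model$base_rate * (if (t == trans[[b]]) kappa else 1) / (kappa + 2)
      w_is <- b %in% strong
      t_is <- t %in% strong
      if (!w_is && t_is) w <- w * model$ws_bias
      in_gbgc <- !is.null(anchor) && model$gbgc_window > 0 &&
        abs(i - 1 - anchor) <= model$gbgc_window
      if (in_gbgc) {
        if (!w_is && t_is) w <- w * (1 + model$gbgc_strength)
        if (w_is && !t_is) w <- w * (1 - model$gbgc_strength)
      }
      is_cpg <- (b == "C" && i < n && chars[i + 1] == "G") ||
        (b == "G" && i > 1 && chars[i - 1] == "C")
      in_hypo <- !is.null(anchor) && model$hypomethyl_window > 0 &&
        abs(i - 1 - anchor) <= model$hypomethyl_window
      is_cpg_ts <- is_cpg && ((b == "C" && t == "T") || (b == "G" && t == "A"))
      if (is_cpg_ts && !in_hypo) w <- w * model$cpg_multiplier
      total[i] <- total[i] + w
      if (is_cpg_ts) cpg_ts[i] <- cpg_ts[i] + w
    }
  }
  list(total = total, cpg_transition = cpg_ts)
}

# Fourfold-degeneracy of a codon by brute translation of all four third
# bases (standard genetic code via Biostrings).
brute_is_fourfold <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aas <- vapply(c("A", "C", "G", "T"), function(b) {
    gc[[paste0(substr(codon, 1, 2), b)]]
  }, character(1))
  length(unique(aas)) == 1
}

# Small synthetic genome shared by several tests.
make_test_genome <- function(n_genes = 20, length = 400000, seed = 7,
                             peak = gc_peak_spec(amplitude = 0.25,
                                                 sigma = 500),
                             min_gap = 6000) {
  simulate_genome(
    genome_spec("chrT", length, background_gc = 0.41, seed = seed),
    gene_plan(n_genes, min_intergenic_gap = min_gap),
    peak = peak
  )
}
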