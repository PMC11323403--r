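#' Reverse-complement a DNA string
#'
#' Transcript-orientation extraction for minus-strand genes relies on this.
#' `N` is preserved; gaps (`-`) are preserved in place.
#'
#' @param x Character vector of DNA strings (A/C/G/T/N/-).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# split one DNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Centered sliding-window mean
#'
#' Truncated at the edges: the window shrinks to the available positions and
#' the mean divides by the actual number of non-missing values. `NA` entries
#' (e.g. rates with a zero denominator) are excluded from both numerator and
#' denominator rather than treated as zero.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param window Window width in positions (default 100).
#' @return Numeric vector of `length(x)` smoothed values.
#' @export
sliding_mean <- function(x, window = 100) {
  if (window < 1) abort("`window` must be >= 1")
  n <- length(x)
  if (window == 1 || n == 0) return(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1L - half_lo
  ok <- !is.na(x)
  cs0 <- c(0, cumsum(ifelse(ok, x, 0)))
  cn0 <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  num <- cs0[hi + 1L] - cs0[lo]
  den <- cn0[hi + 1L] - cn0[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# largest-remainder bin boundaries: len positions into n_bins bins, all within
# 1 bp of each other. Returns integer vector of n_bins + 1 cut points (0-based).
bin_boundaries <- function(len, n_bins) {
  round(seq(0, len, length.out = n_bins + 1))
}

# weak/strong classification of a substitution: W = A/T, S = G/C
ws_klass <- function(from, to) {
  s_from <- from %in% c("G", "C")
  s_to <- to %in% c("G", "C")
  dplyr::case_when(
    !s_from & s_to ~ "WS",
    s_from & !s_to ~ "SW",
    s_from & s_to ~ "SS",
    TRUE ~ "WW"
  )
}

# run code with a private RNG stream; restores the caller's RNG state.
# Derived seeds are folded into the 32-bit range.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(abs(seed) %% 2147483646 + 1), code)
}
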