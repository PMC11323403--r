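#' Alignment scoring scheme
#'
#' Linear (per-base) gap penalty; `N` matches nothing and scores as a
#' mismatch.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap Per-base gap penalty (< 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap = -2L) {
  if (match <= mismatch) abort("`match` must exceed `mismatch`")
  if (gap >= 0) abort("`gap` must be < 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap)),
            class = "scoring_scheme")
}

#' Needleman-Wunsch global pairwise alignment
#'
#' Optimal global alignment under a linear gap penalty, with deterministic
#' tie-breaking during traceback (diagonal preferred, then a gap in the
#' second sequence, then a gap in the first).
#'
#' @param seq1,seq2 Non-empty DNA strings.
#' @param scoring A [scoring_scheme()].
#' @param band Optional band half-width: restrict the dynamic program to
#'   `|i - j| <= band` (0 = full matrix). Exact whenever the optimal path
#'   stays inside the band, e.g. for near-identical sequences.
#' @return List with `aligned1`, `aligned2` (gapped strings) and `score`.
#' @export
needleman_wunsch <- function(seq1, seq2, scoring = scoring_scheme(),
                             band = 0L) {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("empty sequence")
  nw_align_cpp(toupper(seq1), toupper(seq2),
               scoring$match, scoring$mismatch, scoring$gap, as.integer(band))
}

#' Progressive trio alignment (ingroup pair, then outgroup to profile)
#'
#' The two ingroup sequences are aligned first; the outgroup is then aligned
#' against the resulting two-row profile, scoring each profile column as the
#' mean of the per-row match/mismatch scores (gap rows score as mismatch).
#' This follows the phylogeny (the ingroups are the close pair) and stays
#' quadratic; an exact cubic sum-of-pairs alignment ([nw3_sp_score()]) exists
#' for short sequences as a reference.
#'
#' Pairwise identities are matches divided by alignment length; gap or N
#' columns count as non-matches.
#'
#' @param seq_in1,seq_in2,seq_out Non-empty DNA strings (two ingroups and
#'   the outgroup).
#' @param scoring A [scoring_scheme()].
#' @param band Optional band half-width passed to both dynamic programs
#'   (0 = full matrix; see [needleman_wunsch()]).
#' @return A `trio_alignment` list: `gapped_in1`, `gapped_in2`, `gapped_out`,
#'   `pairwise_identities` (named: `in1_in2`, `in1_out`, `in2_out`),
#'   `columns`, `score`.
#' @export
align_trio <- function(seq_in1, seq_in2, seq_out,
                       scoring = scoring_scheme(), band = 0L) {
  if (!nzchar(seq_in1) || !nzchar(seq_in2) || !nzchar(seq_out)) {
    abort("empty sequence")
  }
  pair <- nw_align_cpp(toupper(seq_in1), toupper(seq_in2),
                       scoring$match, scoring$mismatch, scoring$gap,
                       as.integer(band))
  prof <- nw_profile_align_cpp(pair$aligned1, pair$aligned2, toupper(seq_out),
                               scoring$match, scoring$mismatch, scoring$gap,
                               as.integer(band))
  g1 <- prof$aligned1; g2 <- prof$aligned2; g3 <- prof$aligned3
  ident <- function(x, y) {
    cx <- seq_chars(x); cy <- seq_chars(y)
    mean(cx == cy & cx %in% c("A", "C", "G", "T"))
  }
  structure(
    list(gapped_in1 = g1, gapped_in2 = g2, gapped_out = g3,
         pairwise_identities = c(in1_in2 = ident(g1, g2),
                                 in1_out = ident(g1, g3),
                                 in2_out = ident(g2, g3)),
         columns = nchar(g1), score = prof$score),
    class = "trio_alignment"
  )
}

#' @export
print.trio_alignment <- function(x, ...) {
  cat(sprintf("<trio_alignment> %d columns; identities %s\n", x$columns,
              paste(sprintf("%s=%.3f", names(x$pairwise_identities),
                            x$pairwise_identities), collapse = " ")))
  invisible(x)
}

#' Apply the alignment identity gate
#'
#' Pass if the minimum (default) or mean of the three pairwise identities is
#' at least `threshold` (inclusive). The 60% default mirrors the customary
#' alignment-quality cutoff for between-species trio alignments.
#'
#' @param alignment A `trio_alignment`.
#' @param threshold Identity threshold in \[0, 1\].
#' @param mode `"min"` (conservative, default) or `"mean"`.
#' @return `TRUE` or `FALSE`.
#' @export
identity_gate <- function(alignment, threshold = 0.60,
                          mode = c("min", "mean")) {
  mode <- match.arg(mode)
  ids <- alignment$pairwise_identities
  stat <- if (mode == "min") min(ids) else mean(ids)
  stat >= threshold
}

#' Exact sum-of-pairs score of a three-sequence alignment problem
#'
#' Full cubic dynamic program over all three sequences; exponential in
#' neither but cubic in length, so intended for short sequences (reference
#' implementation for validating [align_trio()]).
#'
#' @param seq1,seq2,seq3 DNA strings.
#' @param scoring A [scoring_scheme()].
#' @return The optimal sum-of-pairs alignment score.
#' @export
nw3_sp_score <- function(seq1, seq2, seq3, scoring = scoring_scheme()) {
  nw3_sp_score_cpp(toupper(seq1), toupper(seq2), toupper(seq3),
                   scoring$match, scoring$mismatch, scoring$gap)
}

#' Sum-of-pairs score of an existing trio alignment
#'
#' Scores the given (already gapped) columns: character pairs score
#' match/mismatch (N as mismatch), character-gap pairs score the gap penalty,
#' gap-gap pairs score 0.
#'
#' @param alignment A `trio_alignment`.
#' @param scoring A [scoring_scheme()].
#' @return Numeric score.
#' @export
trio_sp_score <- function(alignment, scoring = scoring_scheme()) {
  c1 <- seq_chars(alignment$gapped_in1)
  c2 <- seq_chars(alignment$gapped_in2)
  c3 <- seq_chars(alignment$gapped_out)
  pair <- function(x, y) {
    both_gap <- x == "-" & y == "-"
    one_gap <- xor(x == "-", y == "-")
    has_n <- (x == "N" | y == "N") & !both_gap & !one_gap
    ifelse(both_gap, 0,
           ifelse(one_gap, scoring$gap,
                  ifelse(!has_n & x == y, scoring$match, scoring$mismatch)))
  }
  sum(pair(c1, c2) + pair(c1, c3) + pair(c2, c3))
}
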