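---
title: "Methods: simulating and measuring GC-content dynamics around TSSs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring GC-content dynamics around TSSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(gcdrift)
library(dplyr)
```

# The scientific question

Most vertebrate protein-coding genes carry a peak of GC-content around
their transcription start site (TSS). Whether that peak is maintained by
selection or by non-adaptive forces can be read from the *direction* of
current sequence change: if the substitutions accumulating today
systematically replace G/C with A/T (strong-to-weak, S→W), the peak is
decaying toward a lower mutational equilibrium; if weak-to-strong (W→S)
changes dominate, something — in practice GC-biased gene conversion
(gBGC) driven by recombination — is pushing GC up.

`gcdrift` implements the full measurement chain for this question:

1. **metagene profiling** of GC, per-nucleotide, and CpG content around
   anchors (positional profiles, and the mRNA 20-bin, TSS/EIB 41-bin and
   ORF 40-bin schemes);
2. **trio substitution inference**: align two ingroup species plus an
   outgroup (Needleman–Wunsch pairwise core, outgroup-to-profile for the
   third sequence, a 60% identity gate), then assign substitutions to
   lineages by outgroup parsimony and aggregate net GC change and
   per-type rates in sliding windows;
3. **de novo mutation (DNM) mapping** onto TSS windows with CpG-context
   classification;
4. **resampling statistics**: Wilcoxon signed-rank bin contrasts and a
   label-shuffling permutation test;
5. a **synthetic genome and trio evolution simulator** that generates
   every input above with a known ground truth, so each stage is
   verifiable without downloading a genome.

Real-data inputs (Ensembl assemblies, CAGE TSS atlases, recombination
maps, published DNM catalogs) are deliberately out of scope; the package
consumes the same file formats (FASTA, GTF, TSV, VCF) from any source.

# The mutation model

`mutation_model()` parameterizes a per-site continuous-time substitution
process:

* **Rate scale.** Each transition has `ts_tv_ratio` (default 2) times the
  weight of each transversion, normalized so an unbiased site mutates at
  `base_rate` per branch-length unit. Branch lengths in
  `simulate_trio()` are therefore expected substitutions per site for an
  unbiased site.
* **AT bias.** All W→S rates (A/T → G/C) are multiplied by `ws_bias`
  (default 0.5). With only this bias the stationary GC fraction is
  `ws_bias / (1 + ws_bias)` ≈ 0.33, i.e. the genome-wide drift toward AT
  that makes GC-rich sequence decay by default.
* **CpG hypermutability.** C→T and G→A rates are multiplied by
  `cpg_multiplier` (default 10) when the site is in a CpG on the current
  sequence — both positions of the palindrome, re-evaluated after every
  applied event. Within `hypomethyl_window` bp of the anchor the
  multiplier is reset to 1, emulating promoter hypomethylation, which
  protects TSS-proximal CpGs from deamination-driven loss.
* **gBGC.** Within `gbgc_window` bp of the anchor, W→S rates are
  multiplied by `(1 + B)` and S→W rates by `(1 − B)` with
  `B = gbgc_strength`. The default `B = 0.4` is the value for which
  transmission odds `(1+B)/(1−B)` equal 70:30, i.e. a 70% repair bias in
  favor of G and C. The window defaults to 0 bp, so the conversion bias
  is off unless a window is requested.

Per site, hit counts are Poisson in the ancestral total rate; hits are
applied sequentially with the base and CpG context re-evaluated before
each, and every event is recorded in a truth table that replays exactly
to the derived sequence. No indels are simulated: the substitution
mapping discards gap columns anyway, and alignment robustness is
exercised separately with explicit gapped fixtures.

## Equilibrium arithmetic and the direction of change

Ignoring CpG effects, the net per-site GC flux at GC fraction $g$ is
proportional to $(1-g)\,w - g$ in units of the S→W rate, where $w$ is
the effective W→S multiplier. Three consequences shape the package's
verification experiments:

* a flat 41% background with `ws_bias = 0.5` sits above its ~33%
  equilibrium, so even "neutral" intergenic loci drift slowly AT-ward;
* a planted TSS peak (amplitude 0.25 over 0.41, i.e. ~66% GC at the top)
  is far above equilibrium and decays clearly faster — the ape/rodent
  regime;
* inside a gBGC window with `B = 0.4`, the equilibrium rises to
  $0.5 \times 1.4 / (0.5 \times 1.4 + 0.6) \approx 0.54$. That is *below*
  a 0.66 peak top, so gBGC of this strength cannot flip the sign of
  change on an already GC-rich peak; it produces net GC *gain* on
  anchors whose GC lies below 0.54. The gain-under-recombination
  experiment therefore runs gBGC windows on flat-background anchors —
  the situation of lineages whose TSS regions recombine and are still
  climbing toward a higher equilibrium — rather than on top of a
  fully-built peak.

# Coordinate and binning conventions

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
is converted at the I/O boundary. Position 0 of every anchored window is
the TSS base itself, negative offsets are upstream, and minus-strand
genes are reverse-complemented so positive offsets always run 5′→3′ into
the gene. Minus-strand gene models store exons in genomic order;
transcript orientation is resolved at extraction time.

The 41-bin TSS/EIB scheme normalizes each gene to its first-exon length
L: 20 bins across the 2L bp upstream, one bin at the TSS, 10 exonic and
10 intronic bins. The TSS bin is the single TSS nucleotide, and the 10
exonic bins partition the *full* exon (the TSS base also begins exonic
bin 22). This is the only layout in which all non-TSS bins are equally
sized at L/10 while every bin is non-empty for any L ≥ 10; carving the
10 exonic bins from the L−1 bases after the TSS would leave an empty bin
exactly at L = 10. When a length is not divisible by its bin count, bin
boundaries come from rounding cumulative fractions, keeping all bins
within 1 bp of each other. Ambiguity characters (N) are excluded from
both numerator and denominator everywhere; isoform weights average
within genes, and the profile mean across genes is unweighted.

`sliding_window()` (default 100 bp, matching the figure convention of
the analyses this package supports) is a centered moving mean that
truncates at the edges and drops undefined positions (e.g. rates with a
zero denominator) from both numerator and denominator — an offset with
no mutable bases is *undefined*, not zero.

# Alignment and substitution inference

The pairwise core is an exact Needleman–Wunsch dynamic program with
linear gap penalty and deterministic traceback tie-breaking (diagonal,
then gap in the second sequence, then gap in the first). Default scores
are match +1, mismatch −1, gap −2; the values are conventional and
configurable. `N` matches nothing and scores as a mismatch.

Trios are aligned progressively, following the phylogeny: the two
ingroups first, then the outgroup against the resulting two-row profile
(column score = mean of the per-row match/mismatch scores; gap rows
score as mismatch). A full cubic sum-of-pairs DP (`nw3_sp_score()`)
serves as the exact reference for short sequences; at the low divergences
relevant here the progressive result matches it. An optional band
(`band` argument) restricts the DP to `|i−j| ≤ band`; the result is
identical to the full matrix whenever the optimal path stays inside the
band, which indel-free input guarantees, and large window sets use
`band = 100` for speed.

The identity gate passes an alignment when the *minimum* of the three
pairwise identities (matches / columns, gaps and N counting as
non-matches) is at least 0.60 — the conservative reading of a 60%
alignment cutoff; mean-identity mode is available.

Substitutions are inferred per column by strict outgroup parsimony: with
ingroups $a, b$ and outgroup $o$, a call is made only when $a \ne b$ and
$o$ equals exactly one of them; the matching ingroup keeps the ancestral
state and the other lineage carries the event. Gap/N columns and
all-different columns are discarded. Event positions are reported in
each ingroup's own ungapped coordinates relative to the anchor. CpG
context is evaluated on the *inferred ancestral* sequence (the extant
ingroup with called events reverted), so a substitution cannot create or
destroy its own context; rate denominators likewise count ancestral
bases, keeping numerator and denominator self-consistent (extant-base
denominators would mix pre- and post-event states).

A cluster of adjacent substitutions in one lineage can make two
compensating gaps score better than a run of mismatches, producing a
locally gapped alignment of indel-free sequences; the affected columns
are then uncallable by contract. `audit_inference()` quantifies this:
truth events in gapped-alignment loci are reported separately instead of
being counted as inference failures, and at the scales used here such
loci are rare (≤ 1 in 500).

ORF analyses use spliced CDS coordinates ("along the ORF" concatenates
coding exons), require an ATG start and length divisible by 3, and
classify fourfold-degenerate (GC4) third positions on the ancestral ORF.
Per-exon counts require at least 4 coding exons, mirroring the
first-vs-fourth-exon contrast.

# DNM mapping

DNM records (chrom, 1-based pos, ref, alt; SNVs only, indels counted and
skipped) are mapped to every TSS within the 2.5 kb flank, with offsets
and bases strand-adjusted per gene; a DNM near two TSSs counts once per
gene, consistent with per-gene normalization. CpG context is classified
on the reference strand *before* strand adjustment — deamination
chemistry is symmetric across the CG palindrome — and the optional
filter removes CpG-context C→T and G→A records; because both members of
the strand pair are named, the filter is orientation-independent.

# Resampling statistics

The permutation test shuffles the pooled per-gene values into two groups
of the original sizes (1000 times by default, or exhaustively for small
groups) and reports both an empirical p,
$(1 + \#\{|\Delta_{null}| \ge |\Delta_{obs}|\})/(n_{perm}+1)$, and a
Gaussian-tail p fitted to the null. Two-sided is the default (sidedness
is configurable); the two-sided Gaussian p doubles the tail on the
observed side so that relabeling the groups leaves it unchanged.
Monte-Carlo draws sample the smaller group from the sorted pool, which
makes label-swap invariance exact rather than merely distributional.
Internal verification uses the empirical p — it is distribution-free.

The Wilcoxon signed-rank test drops zero differences, mid-ranks ties,
and uses the exact sign-flip null (convolution over the realized rank
multiset, handling mid-ranks exactly) up to 25 effective pairs, then a
normal approximation with tie and continuity corrections. All-zero
differences return W = 0, p = 1.

# What the simulator does and does not emulate

The generator draws each base independently with
P(G or C) = background (41%) plus Gaussian peak contributions at TSSs
(default amplitude 0.25, σ = 500 bp — a ~66% peak top that plateaus to
background within ±2.5 kb, matching the observed shape and scale of
TSS peaks). Gene models are placed greedily left-to-right with bounded
retries, both strands, non-overlapping, with one scored transcript per
gene and a CDS that starts in exon 1, begins with a stamped ATG, and has
spliced length divisible by 3.

Deliberately absent: isochore structure, repeats, chromatin, CpG
islands (dinucleotide correlations; a CpG-enrichment option exists as a
flag but the default model is per-base independent), indels, and
population-level processes (every lineage evolves independently from the
ancestor on a star tree, which is exactly the assumption outgroup
parsimony makes — so outgroup-branch misassignment is measurable, not
hidden). Passing tests therefore demonstrate correctness of the
*measurement chain* under a known process, not realism of any particular
genome. One visible consequence: because the synthetic background lacks
CpG islands, flat intergenic controls carry proportionally more
unprotected CpGs than real intergenic DNA, and their AT-ward drift is
comparatively fast; the TSS-vs-intergenic *difference* in net GC change
is therefore a conservative contrast here (the TSS arm's hypomethylation
protection and its composition-driven excess decay nearly cancel), while
the sign of change at the TSS itself is unambiguous.

# Verification experiments and problem sizes

The test suite builds every fixture in code and verifies each stage
against an independent oracle: recursive-enumeration alignment scores
(≤ 8 bp), the cubic sum-of-pairs DP (≤ 40 bp trios),
`Biostrings::pairwiseAlignment` as a cross-check, sign-flip enumeration
for Wilcoxon p (n ≤ 10), brute-force translation for all 64 codons'
degeneracy, analytic Poisson/binomial intervals from independently
recomputed per-site rates, and the simulator's replayable truth tables
for inference precision/recall. The end-to-end experiments use 500 trio
loci of 5 kb at per-branch divergence 0.002 (ape-like), 200-gene genomes
for peak-recovery fits, and 20,000 DNMs over 100 genes — sizes chosen so
each experiment has clear statistical resolution while the whole chain
reruns in minutes on one CPU. `scripts/acceptance.R` reruns all of them
from scratch and writes the measured numbers as JSON.

# A worked example

```{r example}
g <- simulate_genome(
  genome_spec("chrS", 400000, background_gc = 0.41, seed = 7),
  gene_plan(20, min_intergenic_gap = 6000),
  peak = gc_peak_spec(amplitude = 0.25, sigma = 500))
g

w <- extract_anchor_window(g$sequence, g$genes, flank = 2000)
prof <- positional_profile(w)
autoplot(prof, metrics = "gc", window = 100)
```

```{r trio}
m <- mutation_model(hypomethyl_window = 500)
loci <- simulate_trio_set(40, 5000, m, c(0.002, 0.002, 0.002),
                          peak = gc_peak_spec(0.25, 500), seed = 11)
res <- call_trio_substitutions(loci, band = 100)
series <- net_gc_change_series(res$events, span = 2500, window = 100,
                               n_sources = res$n_sources)
autoplot(series)
```

# Known limitations

* Parsimony undercounts at multi-hit sites; at the divergences used
  (≈ 0.2% per branch) multi-hit sites are ~0.5% of events and every
  residual miscall is audited against the truth table.
* The progressive trio alignment is not guaranteed sum-of-pairs-optimal
  for arbitrary inputs; it is exact in the regime used (low divergence,
  no indels) and validated there.
* The banded DP is exact only when the optimal path stays in the band;
  the default everywhere is the full matrix.
* Affine gap penalties, probabilistic ancestral reconstruction, and
  context-dependent substitution models are out of scope.
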