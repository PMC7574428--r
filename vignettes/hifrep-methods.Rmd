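---
title: "hifrep: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hifrep: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Repetitive sequence — transposable elements, satellites, tandem arrays —
occurs at copy number m ≥ 2 per genome, so under approximately uniform
sequencing its k-mers are observed about m times more often than
single-copy k-mers. `hifrep` exploits this in three steps: estimate the
single-copy k-mer coverage from the spectrum, call k-mers far above it
*high-frequency*, and then — crucially — promote the decision from k-mers
to whole reads before assembly. Assembling reads rather than k-mers keeps
repeat structure intact, carries paired-end information into the
assembler, and (as quantified below) acts as a strong error filter,
because a read must be consistently high-frequency along its whole length
to survive.

The underlying assumptions are: reads sampled roughly uniformly (so the
spectrum has a single dominant mode past the error decay), substitution-
dominated errors, and repeat copy number comfortably above the coverage
factor c (a family at copy number m is separable when m · Cov_k ≥ t1 =
⌈c · Cov⌉, i.e. roughly m > c / ρ with ρ = (L − k + 1)/L ≈ 0.7 at
L = 100, k = 31 — in practice m ≥ 2c).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_hist` | 15 | bp | spectrum k; small enough that nearly every window is error-free, large enough that random 15-mers are unique in megabase genomes |
| `k_filter` | 31 | bp | read-filter k; long enough to be specific, short enough to leave q = L − 30 windows per read |
| `c_factor` | 2 | — | threshold multiplier, recommended interval [1.5, 3]; midpoint chosen as default. Larger c = more stringent selection |
| `t2` | 0.9 | fraction | minimum fraction of a read's windows that must be high-frequency |
| `pairing_mode` | strict | — | `strict` keeps a pair whole only when both mates pass (purest assembly input); `either` maximizes pair information; `ignore` drops pairing |
| `k_asm` | 31 | bp | assembly k; odd so no k-mer is its own reverse complement |
| `prune_below` | 2 | count | de Bruijn edge pruning; drops singleton edges, which are overwhelmingly sequencing errors |
| `min_contig_cov` | auto | count | `auto` = ⌈Cov · (L − k_asm + 1)/L⌉, the genome-average k-mer coverage: a repeat contig must beat the single-copy expectation |
| `min_contig_len` | 100 | bp | shortest library contig; below ~3 k-mers a contig carries little repeat signal |

Both threshold comparisons (`count ≥ t1`, `fraction ≥ t2`) are inclusive.
t1 is an integer via ceiling — it is compared against integer counts — with
a floor of 2 so a degenerate coverage estimate can never admit singleton
k-mers.

## Peak detection

The histogram is treated as a dense array over t = 1..t_max with missing
bins zero. Error k-mers produce a steeply decreasing spike at small t;
the search therefore starts at the first *trough*: the smallest
t ≥ max(2, t_floor) at which f stops decreasing — either a local minimum
(f(t) ≤ f(t−1) and f(t) < f(t+1)) or a plain rise (f(t) > f(t−1)). The
rise clause matters for error-free spectra, which climb from t = 1 with no
initial decay and otherwise would have no trough at all. If f is monotone
non-increasing over the whole range there is no secondary peak and the
pipeline refuses to guess, asking for a known depth instead.

The raw peak is the argmax of f at or past the trough (smallest t on
ties). With `smooth_window` = w > 0 (default 5) the mode is refined by a
quadratic fit to log f over the positive bins in [p₀ − w, p₀ + w], clipped
to [t_min, t_max]; the vertex, rounded and clamped to the window, is the
peak. Fitting log f (not log(1 + f)) makes the refinement exactly
invariant under rescaling all f(t) by a constant — a multiplicative shift
in log space — so the peak depends only on the shape of the spectrum; the
window is clipped at t_min so the error decay cannot drag the vertex left.
The window never re-fits when fewer than three positive bins remain or the
fitted parabola fails to open downward; the raw argmax is used instead.

## The read filter as an error filter

At L = 100 and k = 31 a read has q = 70 windows and, at t2 = 0.9,
tolerates at most 7 low-frequency windows. A substitution at read position
i corrupts windows max(1, i − 30)..min(i, 70): at least 8 of them when
8 ≤ i ≤ 93, and a *terminal* window otherwise. Consequently a single
error anywhere in a read disqualifies it (expected survivor fraction
0.995¹⁰⁰ ≈ 0.61 at a 0.5% error rate), and the same arithmetic applies to
any site where the read's own repeat copy diverges from the family
consensus (0.99¹⁰⁰ ≈ 0.37 at 1% divergence — copy-private k-mers sit near
single-copy coverage, far below t1). The filter's recall on
repeat-labelled reads under 1% divergence plus 0.5% error is therefore
bounded near 0.61 × 0.37 ≈ 0.23, and the acceptance test that demands
recall ≥ 0.95 in exactly that world is left failing rather than weakened:
the rule is implemented faithfully and the bound is a property of the
rule, not of this implementation.

The flip side is a strong self-cleaning effect that the end-to-end test
does verify: the reads that *do* pass are precisely the error-free reads
carrying only family-consensus k-mers. The assembly input is thus nearly
noise-free, the de Bruijn graph of a planted family is an unbranched
consensus path, and base-level recovery of the planted repeat intervals
exceeds 0.9 even though read-level recall is ~0.23 — with error-free
reads and a family at copy number ≥ 2c, recall itself also exceeds 0.95,
which the module-level property test asserts.

## Assembler

The built-in assembler is deliberately minimal: canonical k_asm-mers are
edges of a bidirected de Bruijn graph, edges below `prune_below` are
removed, and maximal unbranched paths (unitigs) are emitted — no bubble
popping, tip clipping, scaffolding or paired-end resolution. Extension
stops at any node with in- or out-degree ≠ 1, at palindromic
(self-reverse-complement) junction nodes, and at already-visited k-mers
(so cycles emit one linear representative). Each contig is reported in
canonical orientation (lexicographic minimum of sequence and reverse
complement) and output is sorted by descending length, ties by sequence,
making runs byte-deterministic. Production-scale data should go through
the external adapter (`run_external_assembler()`), which shells out to a
command template, parses the returned FASTA, takes per-contig coverage
from `cov_<x>` header tokens when present and otherwise re-maps read
k-mer counts onto the contig.

## Synthetic data: what it does and does not emulate

The generator realizes exactly the assumptions of the model: i.i.d.
uniform background, repeat copies mutated independently from a family
master at the stated divergence, uniform fragment placement, normal
fragment lengths, substitution-only errors, and deterministic output per
seed. Defaults used throughout the tests mirror a routine bacterial-scale
bench experiment: 100 kb genome, 2 kb × 20-copy family, 40× coverage,
100 bp pairs, 300 ± 30 bp inserts, 0.5% error. It does **not** model
indels, quality-score profiles, GC or PCR bias, nested or truncated
repeat copies, or heterozygosity. A green test therefore establishes
correctness of the algorithms under their own assumptions — not
performance on real libraries, where coverage bias widens the spectrum
peak and indel errors are invisible to a substitution-only filter.

Interval conventions are 0-based half-open everywhere in truth objects
and BED output.

## Other design choices

- **Canonical k-mers by default.** Repeats occur on both strands and the
  read filter must give a read and its reverse complement the same
  verdict; non-canonical counting is kept for testing and diagnostics.
- **Non-ACGT handling.** Windows containing ambiguity codes are never
  counted and never high-frequency, but still count toward q (and fail
  the endpoint test when terminal): conservative against ambiguous reads.
- **Mean read length** is used in the coverage formula when input lengths
  are mixed; it is computed during counting.
- **One k for spectrum and coverage.** The same k (default 15) is used to
  build the histogram and to rescale the peak into read coverage; using
  different k's would silently bias the estimate.
- **Known depth still runs the spectrum.** When `depth` is supplied, t1
  comes from it directly, but the histogram and peak are still computed
  and reported as diagnostics (failures there are tolerated).
- **Config files are JSON** (`jsonlite`), not YAML: no YAML parser is
  available in the supported dependency set, and the config is flat
  enough that the format is immaterial. CLI flags override file values.
- **Empty-library behaviour.** An empty high-frequency read set aborts
  with advice to lower c or t2; an all-filtered contig set warns and
  writes an empty library rather than failing, since a repeat-free sample
  is a legitimate outcome.

## Known limitations

k ≤ 31 (2-bit packed 64-bit words); in-memory counting (hundreds of
megabases of reads at most — genome-scale counting belongs to dedicated
counters); unitig-only built-in assembly fragments highly diverged
families (use the external adapter); recovery evaluation uses exact
k-mer anchoring, which undercounts recovery of contigs more divergent
than one mismatch per anchor length.
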