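---
title: "Methods: language-model variant effect scores, from likelihoods to benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: language-model variant effect scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plmvep)
```

## The model

A protein language model, given a full amino-acid sequence
$s = s_1,\dots,s_L$, emits for every position $i$ a probability vector
over the 20 canonical amino acids, $\Pr(x_i = a \mid s)$. `plmvep` treats
that conditional-likelihood interface as its backend contract
(`score_sequence()`): one $L \times 20$ matrix of log-probabilities per
sequence, each row log-normalized, produced by a single pass over the
whole sequence (no per-position masking — one call scores all positions,
and one call per window suffices for long proteins).

Three effect scores are derived from it:

* **Missense LLR.** For a substitution $wt \to alt$ at position $i$,
  $\mathrm{LLR} = \log \Pr(x_i = alt \mid s) - \log \Pr(x_i = wt \mid s)$.
  Wild-type self-entries are exactly zero; more negative predicts more
  damaging. `llr_matrix()` materializes all $19 L$ substitutions at once.
* **Indel PLLR.** The pseudo-log-likelihood of a sequence is
  $\mathrm{PLL}(s) = \sum_i \log \Pr(x_i = s_i \mid s)$, and an in-frame
  indel scores $\mathrm{PLLR} = \mathrm{PLL}(s^{mut}) -
  \mathrm{PLL}(s^{wt})$ (`vanilla` mode). `weighted` mode divides each PLL
  by its sequence length before subtracting, guarding against
  length-mismatch bias; `absolute` mode takes $|\mathrm{PLLR}|$, counting
  large likelihood *increases* (e.g. gain-of-function-like changes) as
  potentially damaging too.
* **Stop-gain min-LLR.** A premature stop at position $p$ removes residues
  $p..L$ (we include the substituted residue itself in the lost region;
  the choice is isolated in one place and documented). Its score is the
  minimum missense LLR over all substitutions in the lost region,
  excluding the zero wild-type self-entries — i.e. "how damaging could a
  point mutation in the lost region be at worst". This makes the score
  monotone: an earlier stop can never score higher than a later one.

## Long sequences: tiling and edge weights

Transformer-style models cap input length (1,022 residues for the 650M
model this workflow targets). `tile_sequence()` covers longer proteins
with windows of exactly `window_length`, grown in exact
`window_length − min_overlap` steps alternately from both sequence ends
until the innermost pair overlaps by at least `min_overlap`
(default 511); if it does not, a single centered window is inserted. The
invariants — full gap-free coverage, exact window length, overlap ≥ 511,
at most 3 windows per residue — are enforced by `validate_window_set()`
and property-tested across all lengths up to 10,000. The precise
interleaving of left- and right-anchored windows is under-specified by
those invariants; we fix the construction above and treat the invariants,
not the construction, as the contract.

A variant covered by $k \le 3$ windows gets the weighted average
$(w(i_1) s_1 + \dots + w(i_k) s_k) / (w(i_1) + \dots + w(i_k))$, where
$i_j$ is its 1-based position inside window $j$. The weight is a logistic
function of the distance $d$ to the nearest window edge:
$w = \sigma(\text{steepness} \cdot (d - \text{margin})) + \varepsilon$,
defaults steepness $= 0.1$ per residue, margin $= 127$ residues,
$\varepsilon = 10^{-6}$. Only the sigmoid shape is prescribed by the
source workflow; these constants are our calibration, chosen so that
interior positions weigh $\approx 1$ and the outer ~100 residues of a
window contribute almost nothing, and they are exposed as arguments. The
$\varepsilon$ floor prevents division by zero when a variant's only
covering window places it exactly at an edge. `mean`, `min` and `max`
aggregation modes are retained for comparison; variant-at-center
rescoring is deliberately not a production path (it needs one model call
per variant) and exists only as a test oracle. For $k = 1$ the score is
returned verbatim, which keeps the single-window path bit-identical to
the direct computation.

## Indel scoring on long sequences

If either the wild-type or mutant exceeds the input limit,
`indel_context()` builds matched subsequences: 511 residues upstream of
the indel (or as many as exist), the affected region, and downstream
residues filling the *longer* of the two subsequences to exactly 1,022.
Both subsequences share identical upstream and downstream context, so the
PLLR computed on them isolates the indel. An affected region that cannot
fit in one window with its upstream context is rejected rather than
guessed at.

## The synthetic backend: what it emulates, and what a green test proves

Real model weights are deliberately out of scope; the synthetic backend
(`synthetic_backend()`) makes the whole pipeline testable offline. Logits
at position $i$ for amino acid $a$ are a deterministic integer-hash
function with three parts:

1. a **local component** (scale 1.5) keyed by the 7-mer centered at $i$ —
   content-dependent, so an indel leaves downstream per-position
   probabilities essentially unchanged, as a content-conditioned model
   would;
2. a **global component** (scale 0.02) keyed by a digest of the entire
   sequence and the absolute position — any residue change anywhere
   perturbs every row (bitwise), emulating whole-sequence conditioning
   without destroying locality;
3. a **wild-type bonus**: $+1$ logit outside domains (benign-like LLRs of
   roughly $-3..+2$), and $\log((1-t)/t) + \log 19$ inside a planted
   domain of tolerance $t$, which leaves total non-wild-type probability
   $\approx t$ (tolerance $0.001$ gives substitution LLRs around $-10$,
   the scale of pathogenic variants).

All hash arithmetic stays below $2^{26}$ so double-precision integer math
is exact: scoring is bitwise reproducible across platforms. Rows are
log-softmax-normalized, so the row log-sum-exp is 0 to machine precision.

When an indel is scored, planted domain annotations are remapped through
the edit: a domain whose interval the indel disrupts loses its constraint
in the mutant entirely (its remaining residues revert to the flat
distribution, collapsing the mutant PLL), and domains downstream shift
with the sequence. This encodes the biological intuition that breaking a
domain destroys its sequence constraint, and it is what makes the
"deletion inside a domain scores below a matched deletion outside"
property construction-forced rather than a seed accident. Similarly,
windows of a tiled protein carry the domains fully contained in them,
shifted to window-local coordinates.

What the backend does **not** emulate: epistasis beyond 7-mers,
structure- or family-specific substitution preferences (all non-wild-type
amino acids are exchangeable on average), conservation gradients within a
domain, and real positional calibration of LLR magnitudes. A green test
therefore establishes that the *workflow* — tiling, aggregation, context
windows, PLLR algebra, thresholds, statistics — is correct, not that any
particular biological prediction is.

The context-window correctness check (PLLR via subsequences vs. an
unlimited-length oracle backend) uses tolerance 3: the only term that
does not cancel between the two routes is the global component
(amplitude 0.02 per position, independent signs), whose accumulated
drift over ~1,000 positions has a standard deviation well under 1;
3 is ≈ 6 s.d. of that drift, fixed from this analysis rather than from
observed test values.

## Isoform analysis

The same substitution can sit in different sequence contexts across a
gene's isoforms. Variant-to-isoform mapping is supplied as input (a
table of per-isoform positions with explicit absent markers) — inferring
it from genomic annotation is out of scope. A variant's profile is the
set of per-isoform LLRs with min, max and standard deviation;
isoform-sensitivity requires max $> -7$ (looks benign somewhere), min
$< -8$ (looks pathogenic somewhere) and a gap $> 4$, all strict,
matching the printed inequalities; the single-threshold classification
boundary is $-7.5$. The cross-isoform "highly variable" flag is
s.d. $> 2$. We use the population s.d. (divisor $n$); the source does
not state its convention, and with two isoforms the population s.d. is
half the score gap, which makes the boundary case (gap 4 ⇒ s.d. exactly
2 ⇒ not flagged) exactly consistent with the strict inequality. All five
constants live in `sensitivity_thresholds()`.

## VUS mixtures

The unlabeled (VUS) score distribution is decomposed two ways:

* `fit_two_component_gmm()` — free two-Gaussian EM. Initialization is a
  median split plus 4 seeded jittered restarts (best likelihood kept);
  convergence at relative log-likelihood change $< 10^{-8}$ or 500
  iterations; component s.d. floored at $10^{-3}$ to prevent collapse;
  components are reported higher-mean-first so the benign-like fraction
  is always `weights[1]`.
* `fit_fixed_class_mixture()` — each component frozen at the mean and
  population s.d. of labeled benign/pathogenic scores; only the mixing
  weight is fitted. With fixed components the likelihood is unimodal in
  the weight, so the EM fixed-point and a golden-section search agree
  (both are implemented; their agreement is a test).

The free fit is the natural choice when no labeled reference is trusted
(missense VUS); the fixed-class fit is preferable when labeled class
distributions are available and the question is only the mixing
proportion (in-frame indel VUS).

## Evaluation statistics

All scores are "lower = more damaging" and pathogenic is the positive
class; metrics internally negate scores so standard higher-ranks-positive
machinery applies. ROC-AUC uses midranks (ties count ½), making it the
exact Mann–Whitney statistic; a brute-force pair-enumeration oracle
checks equivalence in the tests. The gene-average ROC-AUC averages
per-gene AUCs, unweighted, over genes with at least one variant per
class. Balanced PRC-AUC draws `floor(0.8 × minority)` variants per class
without replacement, 100 times, and averages; this removes the metric's
imbalance sensitivity (duplication of the majority class moves it by
less than 0.01 in the acceptance suite). The permutation test shuffles
scores across variants (one shared permutation per iteration applied to
both methods — the choice that makes identical methods give $p = 1$ and
keeps null p-values uniform on a fixed one-sided tail; independent
per-method shuffling is available as an option) and reports the
one-tailed empirical $p$, printed as $< 1/n$ at zero exceedances.
Bootstrap uncertainty resamples 140 + 140 variants for 20 iterations
(with replacement only when a class is smaller than the draw, flagged).
DMS evaluation computes per-assay Spearman correlations (optionally
after the $x \to |x - x_{WT}|$ transform for assays where deviation from
wild type in either direction is deleterious), then per-gene means, then
the mean of per-gene means; assays within a gene are weighted equally
regardless of size. Alignment baselines: hand-rolled Levenshtein DP
(checked against `utils::adist`), and global alignments via
`Biostrings::pairwiseAlignment` — flat match 2 / mismatch −1 with a
linear gap penalty of 1 per residue (the gap penalty is not printed in
the source; 1 is our configurable default), and BLOSUM62 with affine
gaps 11/1.

## The fixture generator as a stated world

`generate_fixtures()` emits a reproducible bundle: proteins of uniform
length 150–400 (desk-scale but structured like real single-domain
proteins) each carrying one 40-residue domain of tolerance 0.001;
a labeled benchmark whose class scores are drawn from
$\mathcal N(-3, 1.5^2)$ (benign) and $\mathcal N(-12, 2^2)$ (pathogenic),
300 + 300 variants, plus a degraded comparator method (score + noise);
three exon-skipping gene groups where a 60-residue excision truncates
the domain, so the short isoform loses the domain constraint — variants
in the retained domain head are scored by the backend as pathogenic in
the full isoform and benign in the skipped one, which is exactly the
isoform-sensitivity signature; and DMS-like tables whose measurements
are a logistic transform of planted effects plus noise. These defaults
are the stated world of the acceptance suite and were fixed before the
tests were run; the generator's parameters are all recorded in the
bundle manifest.

## Degenerate inputs and numerical choices

* Non-canonical residues (`U`, `X`, `B`, `Z`, `*`, …) are rejected by
  default, naming the position; an opt-in sanitizer maps them to a
  placeholder and records the affected positions. Their likelihoods are
  undefined by the model contract, so silent acceptance would be wrong.
* No-op indels (mutant identical to wild type) are rejected at
  `apply_indel()`; the PLLR-of-identity-is-zero identity is still
  checked directly on PLL values.
* A stop at the last position loses one residue; `residues_lost()` is
  inclusive of the substituted position.
* The 50-bp rule is strict ("more than 50 nt upstream of the last
  exon–exon junction within the CDS"): exactly 50 nt does not trigger
  NMD, and a single-exon CDS never does.
* Scores are written with 4 decimal places in TSV outputs; JSON reports
  keep full precision.

## Known limitations

Frameshifts, nucleotide-level consequence calling, splice-disruption
prediction and genomic liftover between isoforms are out of scope. The
real-model adapter is a contract, not a shipped implementation; all
shipped results come from the synthetic backend and inherit its
simplifications listed above.
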