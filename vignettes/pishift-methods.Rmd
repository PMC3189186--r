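---
title: "Methods: modeling isoelectric-point divergence between orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling isoelectric-point divergence between orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pishift)
```

This vignette is the package's own account of its science: the charge model
and its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, the
numerical choices, and the known limitations. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The charge model

A protein in solution carries ionizable groups whose protonation state
depends on pH. `pishift` uses the sequence-only Henderson–Hasselbalch
model: each group contributes a fractional charge

$$z_\text{base}(x) = \frac{1}{1 + 10^{\,x - pK_a}}, \qquad
  z_\text{acid}(x) = \frac{-1}{1 + 10^{\,pK_a - x}},$$

and the protein's net charge at pH $x$ is the count-weighted sum over
groups. Seven residue types ionize — R, K, H as bases, D, E, C, Y as acids
— plus the free amino and carboxy termini of the mature chain. The default
pKa values (R 12.48, K 10.54, Y 10.46, C 8.18, H 6.04, E 4.07, D 3.90;
N-terminus 8.0, C-terminus 3.1) are a published sequence-pI scale and are
deliberately fixed as the package default so results are comparable run to
run; alternative published scales (e.g. EMBOSS-style) can be swapped in via
a three-column TSV (`read_pka_table()`); `inst/extdata/pka_emboss.tsv`
ships as an example.

**Assumptions.** All groups titrate independently with their model pKa:
there are no microenvironment shifts from folding, no coupled titrations,
no bound ions. `X` and any non-ionizable residue contribute nothing. A
cleaved protein exposes a new N-terminus, which receives the N-terminal
pKa — the pI is always computed on the mature (signal-cleaved) chain, which
matters because secreted proteins are precisely the ones with signal
peptides.

Because every term of the net charge is strictly decreasing in pH, the
whole curve is strictly decreasing, so the isoelectric point — the pH of
zero net charge — is unique whenever the group set contains both
polarities. `isoelectric_point()` solves it by bisection:

* initial bracket 0–14, widened once to −2–16 if the charge has not changed
  sign (compositions dominated by strong acids or bases can have roots
  slightly outside 0–14);
* iteration cap 200; the loop stops when the bracket is narrower than
  `precision` (default 0.01 pH), so the returned midpoint is within
  0.005 of the true root;
* a mid-point charge of exactly zero returns immediately (tie behavior);
* a one-polarity group set raises `"no isoelectric point in bracket"`
  rather than returning a boundary value;
* `protein_pi()` reports the result rounded to 2 decimals, matching the
  solver's precision — unrounded values would suggest accuracy the model
  does not have.

The engine is verified two ways in the test suite: against closed forms
(a peptide whose only groups are the termini has pI exactly
$(pK_{a,\text{N}} + pK_{a,\text{C}})/2$) and against an independent
brute-force scan of the charge curve on a 0.001-pH grid for 1,000 random
sequences (agreement within 0.01 pH).

## Post-translational modifications

Phosphorylation adds a phosphate mono-ester, a two-proton acid. The model
adds **two acidic groups per phospho site**, pKa 1.2 and 6.5 — standard
textbook constants for the first and second phosphate dissociation — so a
phosphosite lowers the pI, never raises it (a property test asserts this).
The site's own residue keeps its groups: serine/threonine phosphosites are
on non-ionizable residues anyway.

Glycosylation is charge-neutral by default: neutral sugars do not titrate.
Sialylated glycans do carry carboxyls, so an exploratory
`sialic_per_glyco` parameter (acid, pKa 2.6) lets each glyco site
contribute that many acidic groups; the default of 0 reflects that sialic
acid counts per site are rarely known. Both parameters live in
`build_groups()` and in the pipeline config.

PTM evidence is a closed vocabulary (`experimental`, `by_similarity`,
`potential`), and `attach_ptms()` can filter on it, so an analysis can be
restricted to experimentally verified sites only.

## The shift threshold

For a species pair, `pairwise_diffs()` gives one absolute pI difference per
ortholog family present in both species. The distribution of such
differences follows no standard law, so significance is defined
non-parametrically:

$$\text{threshold} = 2 \times (Q_3 - \text{median})$$

of the differences, with families **strictly above** the threshold flagged.
Quantiles use linear interpolation of order statistics at plotting
positions $(k-1)/(n-1)$ (R's type 7) — the convention is stated because
quartiles of small samples are otherwise ambiguous; under it the toy vector
`{0.0, 0.1, 0.2, 0.3, 1.0}` has median 0.2, $Q_3$ 0.3, threshold 0.2,
which the tests pin down. The statistic is order-invariant and
scale-equivariant (`threshold(c·d) = c·threshold(d)`), both property-tested.

It is important to understand what this statistic *is*: a robust spread
measure of the upper half of the difference distribution. For any fixed
continuous background shape it sits at a fixed quantile — for a half-normal
at $2(\Phi^{-1}(0.875)-\Phi^{-1}(0.75))\sigma \approx 0.95\sigma$, above
which 34.1% of the mass lies. It therefore flags a *proportion* of the
background, not a fixed effect size; see "Known limitations".

## Permutation significance

"Randomly assigning pI values to proteins" is implemented by shuffling one
species' pI vector across families while the other stays fixed, then
recomputing the statistic of the family under test. Two statistics are
offered because the natural-language description is ambiguous:

* `mode = "protein"`: the family's absolute difference itself. This asks
  whether the observed ortholog pair is more divergent than random
  *re-pairings* of proteins — a stringent null, because random pairings
  mix unrelated families whose baseline pI values differ a lot.
* `mode = "threshold"`: the family's difference minus the threshold
  recomputed from the permuted differences. This asks whether clearing the
  threshold is itself surprising.

Neither mode is asserted to be "the" published procedure; both are exposed
and seed-reproducible. When `factorial(n_families) ≤ n_perm` the
implementation enumerates all permutations and returns the exact tail
fraction (the identity permutation keeps it positive); otherwise it draws
`n_perm` shuffles and uses the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_\text{perm}+1)$, which lies in
$[1/(n_\text{perm}+1),\,1]$ by construction. The exhaustive path is
verified against an independent hand enumeration in the tests.

## Selection enrichment

Sites with selection p-value ≤ α **and** ω > 1 are called positively
selected — the ω condition matters because a small p-value with ω < 1
indicates purifying selection. α defaults to 0.05 and is deliberately not
hard-coded to any particular analysis' cutoff.

A site is "charged" when the **reference species'** residue at that
alignment column is one of the seven ionizable residues; columns where the
reference shows a gap are excluded from both margins (a gap has no residue
whose charge could be affected). Per-column consensus classification was
considered and rejected: the enrichment question is about sites that affect
the charge of one protein whose pI shifted.

The 2×2 table (charged/neutral × selected/background) is tested with a
one-sided Fisher exact test for over-representation of selection among
charged sites; the p-value is the hypergeometric tail, which the test suite
verifies against an explicit binomial-coefficient enumeration for **every**
table with total ≤ 30. A chi-squared variant (`test = "chisq"`) is exposed
for comparison but the exact test is the default — the interesting tables
are small. Alongside the p-value the result carries both selected
fractions, the sample odds ratio $ad/bc$, the exact-test 95% confidence
interval, and `expected_random` — the overall selected fraction, i.e. the
per-class rate expected if selected sites were scattered at random.

## Parsimony on the species tree

pI values discretize to `acidic` (< low), `basic` (> high), `neutral`
(inclusive in between). The default bounds 6.8/7.2 bracket neutrality
around pH 7; they are an invented default (field usage is informal about
"acidic/basic"), configurable everywhere and echoed in pipeline output.
Values exactly on a bound are neutral — a deterministic convention the
tests pin.

The minimum number of category changes on a rooted species tree is computed
by unit-cost dynamic programming over the tree (Sankoff with 0/1 costs)
rather than the classical intersection/union procedure, because the DP is
exact on multifurcating trees while plain Fitch is only guaranteed on
binary ones. Equality with exhaustive enumeration over all internal-state
assignments is property-tested on random trees with up to 6 leaves. States
are unordered: acidic → basic costs the same as acidic → neutral, which is
the assumption to revisit if one believes pI evolves gradually.

## Synthetic data: the stated world

`simulate_proteome()` emulates the structure of a proteome-scale ortholog
comparison: ~10³ families, a bimodal family base-pI distribution (an acidic
mode near 5.5 and a basic mode near 8.6, mimicking the familiar two-humped
proteome pI histogram), per-species drift of the base value by
$|N(0, \sigma)|$ with random sign (default σ = 0.2 pH), and a handful of
planted outlier families whose second species is shifted by an exact target
amount (default three families at 2.0 pH). Values are rounded to 2 decimals
like everything the pI engine reports. The generator returns its ground
truth so recovery can be measured, and is bit-reproducible under a fixed
seed.

What it does **not** emulate: correlation between species (each drifts
independently), missing data, the dependence of pI variance on protein
length, or any sequence-level mechanism — it draws pI values directly.
`simulate_family()` is the sequence-level counterpart for small examples:
it builds an ancestral random protein and mutates designated species to
target pI values, so the whole pipeline (FASTA in, reports out) can be
exercised on data where the truth is known.

`plant_selection_sites()` draws site charge classes Bernoulli(0.3) — about
the ionizable fraction of real proteins — selection flags with
P(selected | neutral) = 0.05 and the odds multiplied by a configurable odds
ratio at charged sites, and emits p-values and ω consistent with the binary
call (p ≤ α and ω > 1 iff selected). The p-values are *not* drawn from a
likelihood model: the enrichment stage consumes only the call, so modeling
the null distribution of a selection statistic would add realism nothing
downstream uses.

A green test on this world therefore establishes: the statistics are
computed correctly (oracle agreement), planted effects of the stated sizes
are detected (power), and null worlds are not over-called (type-I error
≤ 0.07 at nominal 0.05, exact-test conservatism included). It does not
establish anything about alignment quality, ortholog calling, or selection
inference, all of which are upstream inputs here.

### Mutating a sequence to a target pI

The simulator needs real sequences with prescribed pI values. A naive
greedy hill-climb over single substitutions stalls: on short sequences the
pI landscape is coarse (for a glycine decamer, reaching pI 4.5 requires
roughly the composition 4×H + 4×D + 1×E, separated from simpler
compositions by ridges of ~0.5 pH), and any score based on the solved pI
inherits the bisection's 10⁻² quantization, producing huge plateaus of
tied moves. The implementation instead uses the model's own structure: the
pI equals the target exactly when the net charge *at the target pH* is
zero, and that residual is **linear** in the residue counts. It enumerates
all (basic-type, acidic-type) count pairs on a bounded grid, ranks them by
absolute residual, and polishes the leaders with single ±1 count moves
until the charge changes sign inside `target ± tolerance` — an exact
acceptance test, since the charge curve is strictly decreasing. The final
composition is written onto the sequence by converting randomly chosen
(seeded) positions between the neutral and charged classes; length is
preserved and only charged↔neutral substitutions occur, both
property-tested. `tolerance` must be at least 0.02 — twice the solver
precision — because a tighter target cannot be certified. Unreachable
targets (e.g. pI 13.9) raise a condition carrying the best achievable pI.

## Numerical and degenerate-input conventions

* Quantiles: type 7 everywhere; thresholds need ≥ 4 differences.
* Flagging: strict inequality, so a zero threshold (constant differences)
  flags only genuinely divergent families.
* Bisection: bracket 0–14 → −2–16, cap 200, midpoint return, 2-decimal
  reporting.
* Permutations: single integer seed; RNG state is restored after use, so
  library calls do not perturb a caller's stream.
* Enrichment: zero selected sites gives p = 1 and `expected_random` 0;
  zero classified (non-gap) sites is an error; odds ratio 0/0 is NaN,
  x/0 is Inf.
* FASTA: `*` stop symbols are stripped with a warning; any residue outside
  the 20 standard letters plus X is an error naming the record (fail fast
  over silent coercion). Ragged alignments error with the offending row
  lengths.
* Cleavage: ids missing from the cleavage table default to position 0 (no
  signal peptide) with a warning; PTMs inside a removed signal peptide are
  dropped with a warning.
* Coordinates are 1-based inclusive throughout, including alignment
  columns and PTM positions.

## Known limitations

**Exact outlier recovery is impossible under this threshold.** The
acceptance suite contains one deliberately failing test: "exactly the three
planted outliers flagged among 1000 families". Because
$2(Q_3-\text{median})$ sits at ≈ 0.95σ for a half-normal background and
the statistic is scale-equivariant, ≈ 34% of background families exceed it
for *any* σ — the planted outliers are always recovered (sensitivity 1,
tested green), but never alone. Exact recovery would need an upper-fence
statistic (e.g. $Q_3 + 3\,\text{IQR}$) at ≈ 3.9σ, which would be a
different method. The failing test is kept, rather than weakened, as a
precise record of this property; the companion green test asserts the true
behaviour including the analytic 34.1% background exceedance.

Other limitations: the charge model ignores structure (no pKa shifts, no
disulfides — a cystine pair should contribute no C groups but is counted
as two); the permutation null treats families as exchangeable; no
multiple-testing correction is applied across families (deliberately, to
keep the threshold interpretation plain); ancestral-state reconstruction
for continuous pI is out of scope — the parsimony count is over discrete
categories only; and selection inference itself (sitewise dN/dS) is an
input, not something this package computes.
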