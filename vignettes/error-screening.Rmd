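---
title: "Screening clone sequences for PCR misincorporation errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening clone sequences for PCR misincorporation errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrscreen)
```

## The problem

PCR followed by cloning is still the workhorse for discovering members of
multigene families in non-model organisms: conserved primers amplify a mixed
product from several loci or alleles at once, and cloning separates the
mixture one molecule at a time. The price is that cloning captures a *single*
product molecule, so every polymerase misincorporation that molecule
accumulated over the preceding cycles is faithfully sequenced and can
masquerade as a new allele. When the true copy number of the family is
unknown, there is no external way to tell a rare genuine variant from an
artefact — the discrimination has to be statistical.

`pcrscreen` implements that statistical procedure end to end:

1. **calibrate** — estimate the method-specific per-site error rate from
   clones of a locus where every deviation must be an error (a single-copy,
   homoplasmic locus amplified from one individual);
2. **model** — treat the number of errors per clone as binomial;
3. **screen** — group clones of the target family into putative alleles,
   compare observed deviation histograms with the binomial expectation, and
   apply an explicit accept/reject threshold per clone;
4. **validate** — simulate the whole PCR-cloning process with known ground
   truth and confirm that every stage behaves as designed.

## Error definition and rate estimation

Given a gapped multiple alignment of clones, the consensus takes the most
common state among `A, C, G, T, -` per column (`N` never votes; positions
outside a clone's read span do not vote). A *deviation* is any clone state
that differs from the column consensus. Leading and trailing gap runs are
partial-read padding, not deletions; interior gaps are deletion events.
Tied columns are flagged and excluded from deviation calling, so a tie can
never manufacture an error.

The per-site rate is the observed frequency

$$ f = \frac{\text{deviations}}{\text{comparable bases}}, $$

where the denominator counts, for every clone, the non-`N` columns between
its first and last non-gap column — including deletion columns, because an
observed deletion event needs a denominator site. The per-site
per-duplication misincorporation rate follows Hayes' conversion

$$ m = \frac{2f}{d}, $$

with $d$ the number of template doublings. Two modelling decisions matter
here and are deliberate:

* **Only pre-cloning cycles count toward $d$.** Errors arising in the
  post-cloning (colony) PCR start from a large population of identical
  templates and almost never reach fixation in the sequenced product, so
  they are invisible in practice.
* **$d$ defaults to the cycle count** (35 in the calibration protocol this
  package mirrors). True doublings are fewer because amplification
  plateaus — reported quantifications give roughly 16.6 doublings in 25
  cycles — so using the cycle count *underestimates* $m$; the estimate is
  conservative. `d` is real-valued so an effective doubling count can be
  supplied instead.

## The binomial clone error model

If each of the $L$ sites of a clone is miscopied independently with final
probability $p$ (the calibrated $f$), the number of errors per clone is
$X \sim \mathrm{Binomial}(L, p)$. Everything downstream is a function of
this model:

* expected error-count histograms for $N$ clones, $N \cdot P(X = k)$,
  rounded half-away-from-zero only for display;
* the error-free probability $(1-p)^L$ — at the calibration rate a 2000 bp
  amplicon is completely error free in under 5% of cases, which is why even
  an accepted allele sequence should be confirmed independently;
* upper-tail probabilities $P(X \ge k)$ used for accept/reject decisions.

The model is evaluated with exact binomial arithmetic in log space (no
Poisson approximation); the test suite asserts normalization to $10^{-12}$
and checks tail values against direct summation oracles.

The default $p$ is the *exact* quotient `n_errors / n_bases`, never a
rounded presentation value; reports round to 3 significant figures at the
last moment. (This is visible in one place: the exact
$m = 2(95/58592)/35 = 9.2650\times10^{-5}$ rounds to $9.27\times10^{-5}$,
while rounding $f$ first gives the conventionally quoted
$9.26\times10^{-5}$.)

## Goodness of fit

Observed deviation histograms are compared with the binomial expectation by
$\chi^2 = \sum (O-E)^2/E$ over bins with $E > 0$. Defaults: bins $k = 0$ up
to the largest observed count (or to the first bin with raw expectation
below 0.5), no pooling; optional pooling of trailing bins with expectation
below 1. Degrees of freedom default to `bins - 1`, appropriate when $p$ was
estimated from *independent* calibration data; `bins - 2` is selectable for
the case where the rate was fitted to the same histogram. Published
per-group $P$ values in this design are not internally consistent about the
df convention, which is exactly why the policy is a visible parameter and
why $P$ values are not used as acceptance targets by the test suite.

## Thresholds: when is a clone a real allele?

For a screen of $N$ clones of length $L$, the package computes the minimal
deviation count $k^\*$ at which a clone should be treated as a genuine
polymorphism. Four criteria are implemented and *none is privileged*:

| criterion | rule |
|---|---|
| `uncorrected` | $P(X \ge k) < \alpha$ |
| `bonferroni_tail` | $P(X \ge k) < \alpha/N$ |
| `familywise_exact` | $1-(1-P(X \ge k))^N < \alpha$ |
| `expected_count` | $N \cdot P(X \ge k) < 1$ |

At the calibration parameters ($N = 82$, $L = 715$, $p = 95/58592$) these
give $k^\* = 4$ (uncorrected), 7 (both family-wise rules) and 5
(expected-count). The commonly quoted working threshold of 6 for this
design is not derivable from any of the four at $\alpha = 0.05$, so the
command-line interface refuses to guess: `--criterion` is mandatory.
Balancing the risk of accepting artefacts against rejecting genuine but
recently diverged alleles (which may differ by fewer than $k^\*$ sites) is
a study-specific decision; for screening many clones jointly the package
also provides Holm's sequential Bonferroni correction, which is uniformly
at least as powerful as the fixed correction.

## Grouping, chimeras and positional profiles

Clones are grouped into putative alleles by average-linkage (UPGMA)
clustering of pairwise raw difference counts over mutually scored columns,
with a contiguous interior gap run counting as one event. Raw counts (not
p-distances) match the natural "more than 100 differences between groups,
fewer than 10 within" framing of allele separation; per-pair scored-column
counts are reported for users who prefer to normalise. Merge heights are
ultrametric (half the linkage distance); the cut level is specified in raw
difference units and defaults to 50, midway between the expected within-
and between-group separations. Groups smaller than `min_group_size`
(default 3) cannot support consensus-based error discrimination and are
set aside as ungrouped.

Two numerical caveats are handled explicitly:

* **Ties** in the merge order are broken deterministically by the
  lexicographically smallest member identifier, so results are
  reproducible across platforms.
* **Partial reads**: the difference count between two short reads with
  little mutual overlap is spuriously small (the triangle inequality does
  not hold on partial overlaps), which can occasionally pull a truncated
  read into the wrong cluster. `cut_groups()` therefore runs one
  consensus-reassignment pass by default (`refine = TRUE`): each grouped
  clone is moved to the group consensus it mismatches least per scored
  column. Group consensuses cover the whole alignment, so this comparison
  is well defined for any read span.

Chimeric artefacts — recombinant molecules formed by template switching
between alleles during multi-template PCR — are flagged by a deliberately
simple, transparent scan: tile the read span with windows (default 100
columns), assign each window to the nearest group consensus counting only
diagnostic sites (columns where the consensuses differ), merge same-group
windows into segments, and call a chimera when two or more segments
assigned to different groups each have at least `min_diagnostic_sites`
(default 5) of matching support. No k-mer or model-based chimera detection
is attempted; the evidence reported (segments, supports, breakpoints) is
meant to be inspected.

A sliding-window profile (default window 100, step 25, mirroring common
nucleotide-diversity practice) reports substitutions per scored site per
sequence along the alignment. Random misincorporation is positionally
uniform; genuine variation concentrates in rapidly evolving regions, so a
flat profile corroborates the error interpretation.

## The simulator: a stated world with ground truth

`simulate_pcr()` implements a branching process: each cycle, every molecule
is copied with probability `efficiency` (default 1, perfect doubling); each
copy inherits its template's mutations and gains fresh errors at
$\mathrm{Binomial}(L, m_{syn})$ sites; with probability `chimera_rate` a
copy switches templates at a uniform breakpoint. After `cycles` rounds,
`n_clones` molecules are sampled without replacement and truncated to read
spans. Every clone carries complete truth: source allele or chimera donors
and breakpoints, each injected error, and its lineage depth.

Choices behind the defaults, made once:

* `cycles = 35`, matching the pre-cloning protocol being emulated.
* `m_syn` is per *synthesis* (molecule-level copying, a documented
  simplification of semiconservative replication); under perfect doubling
  a random final molecule has $\mathrm{Binomial}(d, 1/2)$ synthesis events,
  mean $d/2$, which is what makes $f = m\,d/2$ and hence $m = 2f/d$ the
  right conversion. The test suite closes this loop: estimating
  $\hat m = 2\hat f/d$ from simulated clones recovers `m_syn`.
* `deletion_fraction = 0.03` and an optional transition bias (uniform by
  default; 0.87 as a realistic preset) mirror the observed calibration
  error spectrum of roughly 97% substitutions, predominantly transitions.
* **Read spans**: full length with probability 0.82, otherwise uniform
  length in `[min_read_length, L]` (default minimum 250) at a uniform
  start. This emulates clone reads of 253–761 bp *averaging* ~715 bp of a
  761 bp region — mostly complete with a minority of truncations. A plain
  uniform length distribution would give a mean of about two thirds of the
  amplicon and does not describe that world.
* `initial_copies = 10` per allele. Real reactions template thousands of
  genomic copies; what matters statistically is that with at least 4
  starting molecules no single first-cycle misincorporation ("jackpot")
  can reach a voting majority of the final pool and corrupt a group
  consensus. Ten is a desk-scale stand-in that preserves this property.
* `pool_cap = 1e6` with uniform thinning: $2^{35}$ molecules are not
  representable, and uniform retention leaves the per-molecule lineage and
  error distributions unchanged.
* `chimera_rate` has **no** empirically anchored default (0); no
  quantitative template-switching rate is available for this protocol.

Two engines produce the same sampled-clone distribution: `"branching"`
simulates every molecule explicitly and supports chimeras; `"lineage"`
samples each clone's lineage directly (depth
$\sim \mathrm{Binomial}(\textit{cycles}, e/(1+e))$ at efficiency $e$) and
is exact in the limit where the number of sampled clones is much smaller
than the pool — which is always the case in practice (tens of clones from
$\ge 2^{20}$ molecules). The lineage engine refuses chimera simulation and
is the right tool for large replicate studies; engine agreement is covered
by the test suite.

## What a green test establishes — and what it does not

The simulator emulates misincorporation, partial reads, chimera formation
and clone sampling. It does **not** emulate: base-quality or chromatogram
error (sequencing error is conflated with polymerase error, as in the
calibration design itself), per-cycle efficiency curves or plateau
kinetics, template-dependent error hotspots, heteroplasmy, or nuclear
paralogs (NUMTs). A green recovery test therefore establishes that the
statistical machinery is correct *under the stated model*, not that the
model captures every failure mode of a particular wet-lab protocol. The
calibration step exists precisely because error rates vary substantially
between protocols and enzymes; rates should be re-estimated whenever the
method changes.

## Numerical and degenerate-input policy

* Consensus ties: fixed state order `A < C < G < T < '-'`, recorded and
  excluded from deviation calling.
* Alignment columns are reported 1-based throughout.
* `N` neither votes, nor counts as error, nor enters the denominator.
* Expected-count rounding: nearest integer, half away from zero.
* Goodness of fit requires at least 2 usable bins and a non-empty observed
  histogram; all-zero expectations are rejected.
* Thresholds report an explicit not-attainable result when no $k \le L$
  satisfies the criterion.
* All simulation is reproducible from an integer seed; the global RNG
  state is restored afterwards.
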