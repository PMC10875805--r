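---
title: "Kinase substrate-preference motifs: model, conventions and limitations"
author: "kinamotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinase substrate-preference motifs: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinamotif)
```

## The problem

Protein kinases phosphorylate serine, threonine or tyrosine residues, and a
key determinant of which kinase acts on which site is the amino-acid
sequence immediately surrounding the phosphoacceptor. In vitro
phosphorylation/phosphoproteomics experiments — incubating dephosphorylated
protein mixtures with one recombinant kinase at a time and identifying the
phosphorylated sites by mass spectrometry — yield, for each kinase, a pool
of substrate sites from which its sequence preference can be estimated.

`kinamotif` turns such a kinase-to-phosphosite table into a per-kinase
statistical profile and uses those profiles for two things: **logos /
anti-logos** (which residues are significantly favored or disfavored at each
position) and **kinase ranking** (given a new phosphosite, which kinases'
preferences best match it).

## The model

### Centralized 13-mers

Every site is represented as a 13-residue window, offsets $-6 \dots +6$ with
the phosphoacceptor at offset 0. When the window overhangs a protein
terminus the missing positions are filled with the placeholder `J`. `J` is
never treated as a 21st residue: at each offset it simply reduces the number
of contributing peptides (the *effective n* of that offset), and an offset
observed only as `J` is unusable (probability column all zero, information
zero). Site positions are 1-based, following UniProt convention.

### Probability and information matrices

For kinase $k$ with $n$ peptides, the count matrix $c(i,j)$ tallies amino
acid $i$ at offset $j$ over the fixed alphabet order
`ACDEFGHIKLMNPQRSTVWY`. Probabilities are
$p(i,j) = (c(i,j) + q) / (n_j^{\mathrm{eff}} + 20q)$ with pseudocount
$q = 0$ by default — a nonzero $q$ is exposed for robustness experiments,
but the default keeps 30-sequence profiles faithful to the observed tallies
and matches the $0\log 0 = 0$ convention used below.

Each position's information content is the uncorrected Shannon form

$$R(j) = \log_2 20 - H(j), \qquad
  H(j) = -\sum_i p(i,j)\,\log_2 p(i,j),$$

in bits: 0 for a uniform position, $\log_2 20 \approx 4.32$ for an invariant
one. No small-sample correction term is subtracted; the correction is off by
default and the profiles report the plain plug-in quantity. Letter heights
are $h(i,j) = p(i,j) \cdot R(j)$, so each column's heights sum to $R(j)$.

### Chi-square filtering and anti-logos

A residue enters the displayed logo only if it is significantly enriched
over the background: for each flanking cell we run a 1-degree-of-freedom
goodness-of-fit test on the dichotomy {residue $i$, not residue $i$},

$$\chi^2 = \frac{(o - e)^2}{e} + \frac{(o - e)^2}{n^{\mathrm{eff}} - e},
  \qquad e = n^{\mathrm{eff}} b_i,$$

without continuity correction, at a raw per-cell $\alpha = 10^{-4}$ (no
multiple-testing correction — a single fixed $\alpha$ per analysis).
Significantly depleted cells form the **anti-logo**. The depletion height is
a package convention, since only membership in the depleted set is defined
by the filter: $d(i,j) = \frac{e - o}{n^{\mathrm{eff}}} R_{\mathrm{dep}}(j)$
where $R_{\mathrm{dep}}(j)$ is the Shannon information of the positive
deficits $(e-o)^+$ normalized over the column's depleted cells. Any strictly
positive monotone function of the deficit would order the letters the same
way; downstream code should rely on membership and ordering, not absolute
anti-heights. Offset 0 is excluded from both logo and anti-logo: the
acceptor residue is a class label, not a preference.

### Background

The default background $b$ is the dataset-wide residue frequency over all
flanking offsets of every kinase's peptides (offset 0 and `J` excluded),
floored at $10^{-6}$ and renormalized so chi-square expectations are never
zero. The rationale is that substrate pools from a single in vitro
experiment share one amino-acid composition; `"uniform"` and user-supplied
backgrounds are selectable. The background affects only which cells pass
the significance filter — the heights $h(i,j)$, and therefore the scores,
are background-free.

### Scoring and ranking

A query 13-mer is encoded as a Boolean $13 \times 20$ matrix $x$ ($x(i,j)=1$
iff the query residue at offset $j$ is amino acid $i$; `J` rows all zero)
and scored against kinase $k$ by the dot product

$$M^k = \sum_{i,j} x(i,j)\, h_k(i,j),$$

i.e. the sum over non-`J` positions of the kinase's letter height at the
query's residue, in bits. The scoring matrix is the **unfiltered** heights
matrix including offset 0 (whose one-hot row contributes the height of the
query's acceptor residue); chi-square filtering affects only the displayed
logo. Scores are raw — no normalization by query length or profile size.
Rankings restrict by default to profiles whose class (S/T vs Y, decided by
the majority center residue of the training peptides, ties to S/T) matches
the query's center, mirroring how serine/threonine sites are ranked among
S/T kinases only; `restrict = "all"` is available for exploration. Ties are
broken lexicographically by kinase name so output is deterministic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | `1e-4` | raw per-cell chi-square level for logo membership |
| `min_n` | 30 | minimum peptides per kinase profile |
| `pseudocount` | 0 | probability smoothing (per cell, in counts) |
| `background` | `"dataset"` | reference distribution for the filter |
| `restrict` | `"auto"` | class restriction at ranking time |

`min_n = 30` reflects the point where positional preferences are stable
enough to display; profiles can be forced at lower `min_n` explicitly, with
the caveat that a 13 × 20 table estimated from fewer peptides is mostly
sampling noise (the plug-in $R$ has an upward bias of roughly
$19/(2 n^{\mathrm{eff}} \ln 2)$ bits per position).

## The synthetic generator

Because real profile construction needs a large curated phosphosite table
plus substrate sequences, the package ships a generator that emulates
kinase-specific substrate pools from parameterized position weight matrices:

* four archetype presets — **basophilic** (R/K at −3, −2; the PKA pattern),
  **proline-directed** (P at +1; CDK/MAPK), **acidophilic** (D/E at +1, +3;
  CK2), **tyrosine_acidic** (Y acceptor, D/E across −3..+3; EGFR-like) —
  with a fraction `sharpness` (default 0.9) of each signal column's mass on
  the signature residues and the rest uniform;
* random sharp PWMs with three single-residue signal columns, emulating a
  panel of distinct kinases;
* `make_benchmark()`, which embeds sampled peptides in random 50-residue
  host proteins (i.i.d. uniform composition, splice position uniform over
  the protein so terminal `J`-padding paths are exercised) and writes the
  exact site-table/FASTA formats the readers consume, plus a JSON truth map.

Benchmark composition is a real choice. Pair-split presets at sharpness 0.9
carry about 2.4–2.8 bits of consensus signal (two residues share each
column), whereas one sharp random column carries ~2.7 bits; in a mixed panel
a random decoy whose single signal cell happens to coincide with the
consensus query's tie-broken flank residue can therefore outscore a
pair-preset generator. Consensus self-ranking is consequently benchmarked on
the homogeneous random panel (`pwm_set = "random"`, 20 kinases, 100 peptides
each), where recovery is essentially perfect; the mixed panel (default) is
used for format round trips and demonstrations.

What the generator does **not** emulate: mass-spectrometry detection noise,
site-localization ambiguity, compositional bias of real proteomes,
correlated positions within motifs, or shared substrates between kinases.
Passing the synthetic benchmarks therefore demonstrates that the machinery
is correct, not that real-data rankings will place the true kinase first —
on curated in vitro data, closely related kinases share motifs and the
ranked list should be read as a family-level candidate set.

## Numerical choices and degenerate inputs

* $0 \log_2 0 = 0$ throughout; probability columns are validated to sum to
  1 within $10^{-6}$ before entropy is taken.
* Profile serialization writes reals as 17-significant-digit decimal
  strings, which round-trip IEEE doubles exactly; `read_profiles()`
  restores every matrix element bit-for-bit and rejects stores whose
  alphabet or offset range differs from the canonical one.
* Rows of the site table that cannot be resolved (unknown accession,
  position beyond the sequence, non-S/T/Y site) are skipped and tallied per
  reason rather than aborting: large curated tables contain
  isoform/version mismatches, and data-quality transparency beats failure.
  Duplicate observations of one site are retained as separate counts.
* An offset with `effective_n = 0` stays all-zero even under a pseudocount
  (flagged unusable) so terminal padding never manufactures information.
* Chi-square expectations can never be zero because the background is
  floored at $10^{-6}$.

## Problem sizes in the shipped checks

The test suite and the acceptance script work at deliberately modest sizes
chosen to exercise every code path with comfortable statistical margins:
200 peptides per preset for motif recovery, 20 kinases × 100 peptides for
self-ranking, 5 × 40 for store round trips, 2000 draws for frequency
calibration. These are the package's reference conditions; all complete in
well under a minute each.

## Known limitations

* The information matrix uses the plug-in entropy; small-$n$ profiles
  overstate $R$ uniformly across kinases, which cancels in rankings among
  profiles of similar $n$ but not between very different $n$.
* Anti-logo heights are a display convention (see above).
* Whether a production scoring matrix should be chi-square-filtered before
  scoring, and whether offset 0 should contribute, are genuinely open
  conventions; this package scores the dense unfiltered matrix including
  offset 0, and exposes the filtered cells only in the logo model.
* No integration of kinase/substrate co-expression or co-localization —
  sequence preference alone cannot distinguish closely related family
  members.
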