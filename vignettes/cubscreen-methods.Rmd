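---
title: "Codon usage bias screening: models, parameters, and design notes"
author: "cubscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias screening: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubscreen)
```

# The problem

Synonymous codons are not used uniformly. The strength and direction of
this codon usage bias (CUB) differ between organisms, and when two
organisms live in tight association — here the motivating case is a
plant-growth-promoting rhizobacterium colonizing a plant host — genes of
one organism whose codon usage tracks the partner's are interesting
candidates for interaction biology. `cubscreen` provides the complete
chain: per-gene CUB indices, host-adaptation indices, a cross-species
correlation screen, and an expression-response stage, together with a
synthetic-data generator that plants known structure so every stage can be
validated quantitatively.

# Sequence input and quality control

CDS FASTA files are read with Biostrings; the identifier is the header
token before the first whitespace. QC retains sequences that are a
multiple of 3 nt long, contain no internal stop codon and (strict mode)
no ambiguous base, and have at least `min_codons` codons. The default
`min_codons = 30` reflects the instability of ENC and RSCU on very short
genes; it is configurable. Terminal stop codons are accepted but excluded
from all codon counts, because public CDS dumps are inconsistent about
including them; a sequence lacking a terminal stop is kept. QC is
idempotent and reports one removal reason per sequence, checked in a
fixed order (length, ambiguity, internal stop, length-in-codons).

The standard genetic code is used for both organisms: the bacterial code
(translation table 11) differs from table 1 only in start-codon
annotation, which is irrelevant for CDS-internal codon counting.

# Index definitions and numerical choices

**RSCU.** $\mathrm{RSCU}_c = x_c \,/\, \big(\tfrac{1}{k_a}\sum_{c' \in
\mathrm{fam}(a)} x_{c'}\big)$, where $k_a$ is the synonymous family size.
Families with zero observed count yield explicit `NA` entries — never
zeros, which would fabricate anti-bias and inflate downstream
correlations. The 59 "informative" codons (61 sense codons minus ATG and
TGG) form the vector used by the screen and SiD.

**ENC.** Wright's formulation with per-family homozygosity
$F_a = (n_a\sum p_i^2 - 1)/(n_a - 1)$ for families with $n_a \ge 2$,
class means $\bar F_k$ over degeneracy classes $k \in \{2,3,4,6\}$, and
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$. Sixfold
families (Leu, Ser, Arg) are treated as single 6-fold classes, not split
2+4 — other tools differ here, and comparisons should account for it.
Nonpositive $F$ values (possible at small $n$) are dropped from class
means; a missing $\bar F_3$ (Ile unobserved) is imputed as
$(\bar F_2 + \bar F_4)/2$; values above 61 are capped. If any other class
is empty the gene's ENC is flagged undefined and counted in summaries as
an exclusion.

**SCUO.** Entropy-based orderliness per amino acid,
$O_a = (\log_2 k_a - H_a)/\log_2 k_a$, weighted by codon counts. 0 means
uniform synonymous usage, 1 means one codon per family.

**PR2.** The parity plane $x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$ is
computed by default from third positions of the fourfold-degenerate
families only (Ala, Gly, Pro, Thr, Val), where the third base is fully
synonymous; the fourfold boxes of the sixfold families are excluded to
keep the codon set unambiguous. An all-codon mode is provided
(`fourfold_only = FALSE`) since published parity plots do not always state
their convention. Points with a zero denominator are flagged undefined;
quadrant assignment uses strict inequalities, with exact 0.5 labelled
"boundary" and excluded from quadrant counts, so counting is
deterministic.

**CAI.** Reference weights come from the pooled codon counts of the
entire host CDS collection — not a curated highly-expressed subset, which
the motivating workflow did not use; any reference FASTA can be
substituted. Zero reference counts get a 0.5 pseudocount before
$w_c = x_c/\max_{\mathrm{fam}} x$, keeping all weights positive; CAI is
the count-weighted geometric mean of $w$ over informative codons.

**RCDI.** $\tfrac{1}{N}\sum_c \frac{\mathrm{CiF}_a(c)}{\mathrm{CiF}_h(c)}
x_c$ with within-family relative frequencies for gene and host, host
frequencies pseudocounted like CAI. RCDI equals 1 exactly when the gene's
within-family usage matches the host's.

**SiD.** $(1 - \cos\theta)/2$ between two organism-level usage vectors.
The default basis is genome RSCU over the 59 informative codons, matching
the screen's standardization; raw codon frequencies are also accepted
since published SiD values do not always state the basis.

# The similarity screen

Each query gene's RSCU vector is correlated (Pearson) against the
partner's organism-level RSCU profile over the codons defined in both —
undefined entries are pairwise-deleted and $n$ adjusted, never zero-filled.
The p-value uses $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, two-sided, and
selection is $r \ge 0.5$ and $p < 0.05$ with **no multiple-testing
correction** — the published screen's explicit choice, preserved for
fidelity; Benjamini–Hochberg selection is one flag away. Genes with fewer
than 10 usable codons are flagged untestable. An all-vs-all "best-gene"
mode is included because the underlying method description admits either
reading; the profile mode is the default as it yields one test per query
gene, matching how such screens report gene counts.

A calibration caveat, verified by simulation and kept deliberately: RSCU
entries are linearly constrained within each synonymous family (they sum
to $k_a$), so the 59 entries carry roughly 41 effective degrees of
freedom, not 57. The $t$ reference therefore understates the spread of
$r$ under the null, and the nominal 5% level realizes at roughly 10–11%.
This is a property of the published procedure itself; correcting it would
change the method being reproduced. Screen *selection* additionally
requires $r \ge 0.5$, which at 59 codons is far outside the null bulk, so
the practical false-selection rate on unrelated organisms is near zero
(the test suite checks this).

# Expression response

**DEG merging.** Each contrast's two DE tables are thresholded
identically (adjusted $p < 0.05$ and $|\log_2 FC| \ge 1$ — the published
"fold change > 1" is read on the log2 scale, since a raw fold-change
threshold of 1 would be vacuous) and intersected per direction. Genes
called in opposite directions are excluded and reported.

**Model profiles.** All integer profiles of length $T$ starting at 0 with
steps in $[-c, c]$ are enumerated ($(2c+1)^{T-1}$ candidates); $m$
representatives are chosen greedily by maximizing the minimum distance
$d = 1 - r$ to the already-chosen set, in the manner of short time-series
expression mining. Defaults $c = 2$, $m = 50$ follow that software's
conventions. Correlation with the flat profile (zero variance) is defined
as 0, making every non-flat candidate equidistant from flat; the greedy
seed is then the lexicographically smallest non-flat candidate, and all
ties break lexicographically, so the selected set is a deterministic
function of $(T, c, m)$.

**Assignment and significance.** Expression is summarized per group as
the mean of $\log_2(\mathrm{CPM} + 1)$ over replicates (CPM = counts
scaled to per-sample total), expressed as change vectors against the
baseline group, and assigned to the best-correlated selected profile
(zero-variance genes unassigned; ties to the lower profile id). The null
is exact: all $T! = 24$ permutations of each gene's change vector are
assigned by the same rule, expected profile sizes are the summed
per-gene probabilities, and each profile's p-value is the upper-tail
binomial probability of its observed count, Bonferroni-corrected by $m$.
Exact enumeration removes all Monte-Carlo noise at negligible cost for
$T = 4$.

A practical note on per-gene assignment accuracy: with 3 replicates and
NB dispersion $\phi = 0.1$, the group-mean $\log_2$ noise is about 0.26
per group regardless of expression level
($\sqrt{\ln(1+\phi)}/\ln 2/\sqrt{3}$), and the default $m = 50$ selected
set contains profiles correlated at $r \approx 0.87$ with any given
pattern. Genes planted on a pattern at effect size 2 are therefore
assigned to *that exact profile* about 65% of the time, with most of the
remainder landing on immediate neighbours; the planted profile's *size
test* is nonetheless decisively significant (adjusted $p \sim 10^{-12}$
at 200 planted genes among 2000). Per-gene recovery above 90% would
require either dispersion below ~0.045 or a sparser profile set
($m = 20$ reaches ~88%). This trade-off is inherent to correlation-based
assignment on short series, not an implementation artifact.

**ΔΔCt.** $\Delta Ct = Ct_{target} - Ct_{ref}$ per sample,
$\Delta\Delta Ct$ relative to the control-group mean, fold
$= 2^{-\Delta\Delta Ct}$. The control group's *geometric* mean fold is 1
by construction. Samples missing a reference Ct are dropped with a
warning.

# The synthetic-data generator

The generator emulates the study's data shapes with known truth; its
defaults are the conditions used throughout the tests and the acceptance
script.

**CDS collections.** A codon model holds per-amino-acid codon
probabilities built from a GC3 tilt times a seeded Dirichlet preference
draw (`preference_strength = 5`), so two organisms differ both in GC3 and
in which codon each family prefers — as real organism pairs do. The query
and host models default to GC3 biases 0.38 and 0.58, in the range of the
motivating plant (AT3-rich) and bacterium (moderately GC3-rich) genomes.
Genes draw amino acids from a fixed proteome-like background, lengths
log-normal with median 300 codons (typical of plant/bacterial CDS), and
codons from the per-gene Dirichlet-jittered model (concentration 200,
giving realistic gene-to-gene usage spread). Planted genes use the
mixture $(1-\lambda)\,\mathrm{own} + \lambda\,\mathrm{partner}$, so
"similarity" is continuous in $\lambda$ and recovery curves are
meaningful; sequences always pass strict QC by construction.

**Count matrices.** Negative-binomial counts over 4 groups × 3 replicates
(the study design), gene baselines log-normal around 100 (median
moderately-expressed gene), dispersion 0.1 (typical bulk RNA-seq),
log-normal library factors (sd 0.1). Planted genes multiply their group
means by $2^{\mathrm{effect} \cdot z_t}$ for a profile pattern $z$.

**DEG tables.** Two deliberately different simple recipes fabricate the
two tables the merge step consumes: a gene-wise pooled-variance t-test
and a global-variance log-ratio z-test (per-gene variance replaced by the
median residual variance across genes). A purely rank-based recipe was
considered and rejected: with 3 vs 3 replicates any rank statistic is
information-bounded (the exact 3v3 Mann–Whitney two-sided minimum is
p = 0.1) and essentially never survives BH adjustment at thousands of
genes, which would leave the merged "common" sets empty and the merge
step untested. Both recipes normalize by median-of-ratios size factors:
planted DE genes shift library totals, and total-count scaling would leak
that composition shift into every null gene's fold change. The separate
`simulate_deg_tables()` plants exact common/exclusive/conflicting call
sets for sharp merge tests.

**Ct tables.** Reference Ct around 17, target Ct offset by a base ΔCt of
3 minus $\log_2$ of the group's true fold, technical noise sd 0.05.

All randomness flows through a single user seed; identical seeds give
byte-identical outputs.

# What the synthetic tests do and do not show

Passing tests demonstrate that every formula matches independent
brute-force oracles, that the screen's operating characteristics behave
as designed on data whose generative model is known, and that the profile
machinery's exact null is exactly computed. They do not show that real
CDS collections satisfy the generator's assumptions: real genomes have
expression-correlated CUB, amino-acid composition variation across genes,
isochore/GC gradients, alternative transcripts and pseudogenes, none of
which are modelled. Likewise the NB count generator has no
gene–gene correlation and a single dispersion. Conclusions about real
host–microbe pairs require the real inputs; the published headline
numbers additionally depend on the exact (unversioned) genome assemblies
used, and are not reproducible from code alone.

# Problem sizes

The test suite and the acceptance script use 2000-gene organisms, a
2000 × 12 count matrix, 100-gene oracle sweeps and 20-seed null
replicates — sizes at which every statistical check is stable while a
full run stays in the tens of seconds on a single core.
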