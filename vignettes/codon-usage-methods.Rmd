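---
title: "Codon usage bias and host adaptation: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and host adaptation: models, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
library(dplyr)
```

## The problem

Synonymous codons are not used equally. In viral genomes the observed
bias is shaped by two forces that this package is built to separate and
quantify: *mutation pressure* (directional nucleotide bias that acts on
all codon positions alike) and *natural selection* on codon choice
(translational efficiency, host tRNA pools), which acts mostly on the
synonymous third position. A second, applied question follows: how well
does a virus's codon usage match a candidate host's, and which of several
hosts does it match best? The package implements the standard descriptive
statistics (composition, RSCU, ENC), the mutation-versus-selection
diagnostics (ENC plot, PR2, neutrality regression, RSCU-space PCA) and
the host-adaptation indices (CAI, RCDI, SiD), with a synthetic-cohort
generator that provides ground truth for all of them.

## The 59-codon convention

Every statistic is computed over the 59 *analyzable* codons: the three
stops plus `ATG` (Met) and `TGG` (Trp) are removed before anything is
counted, because codons with no synonymous alternative carry no usage
signal. The 18 remaining amino acids split into families of degeneracy
2 (nine families), 3 (Ile), 4 (five) and 6 (Leu, Ser, Arg). The canonical
codon order — amino acids alphabetically by one-letter symbol, codons
lexicographically within each family — is part of the public contract
(`codon_order()`), so PCA loadings and SiD inner products are
reproducible bit for bit. Codons are keyed internally as DNA (`T`);
RNA spelling is a display option only.

Composition statistics use one consistent denominator: the analyzable
codons. The third-position percentages A3s/C3s/G3s/U3s are therefore
CodonW-style synonymous statistics, and a consequence of the single
denominator is that GC3 and GC3s coincide in this package's output. Both
columns are kept because downstream consumers conventionally expect both
names; field pipelines that mix tools (a full-sequence GC3 from one, a
synonymous GC3s from another) will see small differences we deliberately
avoid. With `basis = "full_cds"`, `composition()` instead reports the
overall base percentages across every base of the raw sequence, while
positional statistics always stay on the analyzable set.

## Statistics and their conventions

**RSCU.** `RSCU_i = g_i * k / sum(g)` within each family. Within every
observed family the values sum to exactly `k`, which is asserted in the
tests with rational-arithmetic-exact inputs. Families a sequence never
uses yield `NA`, never a fabricated 0: short genes (the 6K1/6K2/PIPO
regions of a potyvirus are ~50–60 codons) routinely miss amino acids, and
a zero would poison every downstream inner product. Consumers state their
policy: PCA imputes the neutral value 1 (and reports how many cells were
imputed), SiD drops the codons from the comparison, CAI/RCDI drop the
family. Ties for a family's preferred codon are all flagged, and the
ending-base summary assigns 1/t of a share to each of t tied codons so
the 18-family total is conserved.

**ENC.** Wright's estimator, built from family homozygosities
`F = (nS - 1)/(n - 1)` averaged within each degeneracy class. Families
with n < 2 are skipped from their class mean, as are families whose F is
exactly 0 (uniform usage at minimal counts — the estimator is undefined
there, and including zeros would make a class mean of 0 and an infinite
ENC). If the single 3-fold family (Ile) is unusable, `F3` falls back to
`(F2 + F4)/2`, Wright's own suggestion, so short genes still get an ENC;
if any other class is entirely unusable the sequence gets a flagged `NA`
with the class named — a crash-free cohort run was a hard requirement.
Raw estimates above 61 (common at small n) are clamped to 61 with the
raw value retained in `enc_raw`. ENC ≤ 35 sets the significant-bias
flag. The ENC-plot residual is `enc - expected_enc(gc3s)`, with
`expected_enc(s) = 2 + s + 29/(s^2 + (1-s)^2)`; negative residuals are
the selection signature.

**PR2.** Third-position base ratios `A3/(A3+U3)` against `G3/(G3+C3)`,
restricted by default to fourfold-degenerate families (Sueoka's
construction: only there is the third position entirely free of
protein-level constraint); an `all_codons` scope is selectable for
comparison. A coordinate whose denominator is empty is `NA`, flagged
rather than forced.

**Neutrality regression.** OLS of GC12 on GC3 across sequences, with
Pearson correlation and its two-sided p-value. The slope is reported as
the mutational percentage (`100 * slope`) and its complement as the
selection percentage. Note the estimator detail: because GC3 is itself
estimated from finitely many codons, the OLS slope is attenuated by
regression dilution — about 0.5% at 3000 codons per sequence with the
cohort spread used in the tests. This is inherent to the method (real
studies have it too) and is well inside the 3-standard-error band the
validation uses.

**CAI, RCDI, SiD.** The cohort studies this package serves computed CAI
and RCDI on a web service without printing formulas, so the package pins
concrete published definitions and records them in the documentation:
Sharp–Li CAI (geometric mean of relative adaptiveness
`w = RSCU / max RSCU in family` over all scored codon occurrences) and
the CAIcal RCDI sum `sum((CiFa/CiFh) * N_i / N)` over scored codons,
where `CiFa`/`CiFh` are within-family codon frequencies in query and
host. RCDI ≥ 1 always (Cauchy–Schwarz within each family), with equality
exactly at host-matched usage; both fixed points are asserted exactly.
Whether CAIcal additionally normalizes CAI by an expected-CAI null is
not determinable from the sources we pin to; raw CAI is reported. For
SiD the distance is `D = (1 - R)/2` from the cosine similarity R of the
two RSCU vectors. The source prints the formula ambiguously
(`1 - R^2` is a plausible reading of the typography), but `(1 - R)/2`
is the definition the SiD literature uses and is what identical vectors
(D = 0) and disjoint-support vectors (D = 0.5) pin down; D is quoted on
the conventional 0–1 scale even though non-negative RSCU vectors bound
it at 0.5.

**Host references.** Built from pooled CDS counts or a 64-row usage
table (counts or per-thousand — the scale cancels in every derived
quantity). Families containing a zero count receive a 0.5 pseudocount on
every codon of that family (only then), so CAI never takes log 0 and
RCDI never divides by zero; the pseudocount is a parameter. Families
with zero total stay undefined and are dropped by the scoring functions
with the drop counted. Note the interaction: with the default
pseudocount, a two-codon hand example like counts {3, 1, 0, 0} gives
w = 0.43 rather than the pseudocount-free 1/3; set `pseudocount = 0` to
reproduce textbook arithmetic on complete-support examples.

## The synthetic-data generator

`simulate_cohort()` is first-class, tested code: it defines the
conditions under which every pipeline stage is validated. Three regimes:

* **mutation_only(theta)** — bases are independent within a codon under a
  product measure over the 62 non-stop codons. The naive construction
  (per-base GC probability theta, resample stops) does *not* yield
  measured GC contents of theta: conditioning on "not a stop" and the
  exclusion of `ATG`/`TGG` from the tally shift the per-position GC of
  the analyzable pool, enough to depress the expected neutrality slope
  to ~0.966 — a systematic violation of the regime's defining property.
  The per-position GC weights are therefore calibrated by iterative
  proportional fitting so the analyzable-codon pool has GC content
  exactly theta at every position. That is what "the same mutational
  pressure acting at all three positions" means for the statistics this
  package measures, and it makes the expected slope exactly 1 and the
  expected GC3s exactly `100 * theta`. Neutrality cohorts draw each
  sequence's theta uniformly from [0.3, 0.7].
* **selection(beta)** — amino acids from a fixed profile (uniform over
  the 18 analyzable amino acids by default, which maximizes family
  coverage in short genes); within each family a preferred codon carries
  weight `exp(beta)` (default beta = 1), and a per-sequence
  third-position GC level drawn from [0.3, 0.7] reweights codons. The
  third-position reweighting is applied *within* blocks of codons
  sharing their first two bases, and the block itself is chosen
  independently of that level — without this, the six-fold families
  (where synonymous choice moves first-position bases) would leak the
  third-position signal into GC12 and bias the "slope ≈ 0" property the
  regime exists to produce. ENC falls below the expected curve
  (negative residuals), GC3 varies while GC12 stays flat.
* **host_mimic(host_ref, lambda)** — codons from
  `lambda * host_freq + (1 - lambda) * uniform` within each family;
  expected RSCU is `k * p`, recorded in the cohort's truth attribute.

Every cohort is deterministic for a fixed seed, with per-sequence
substreams derived from (seed, index); a terminal `TAA` is appended so
generated records exercise the terminal-stop tolerance. What the
generator does *not* emulate: phylogenetic correlation between isolates,
recombination, indels, amino-acid composition gradients along a real
polyprotein, and dinucleotide-level constraints (e.g. CpG suppression).
Passing tests therefore demonstrate correctness of the statistics under
known generating forces, not that real cohorts are free of those
confounders.

## Degenerate inputs and numerical choices

* Sequences with ambiguity codes are excluded whole at load, with a
  message; codon-masking would make per-sequence totals uninterpretable.
* A single terminal stop is silently dropped; an internal stop is a hard
  error reporting its codon position (it signals an out-of-frame or
  pseudogenized input). `frame_policy = "trim"` drops a trailing
  incomplete codon for fragment inputs; the default is strict.
* Classification boundaries are strict inequalities: RSCU of exactly 0.6
  or 1.6 is in the unbiased range.
* PCA is covariance PCA (mean-centered, unscaled): RSCU is already
  dimensionless and family-normalized, so correlation scaling would just
  up-weight invariant codons. Axis signs follow a fixed convention (the
  largest-magnitude loading on each axis is positive). A zero-variance
  input returns a flagged degenerate result rather than an error.
* `expected_enc` requires s in [0, 1] as a fraction; cohort tables carry
  GC3s in percent and convert at the boundary.
* Validation problem sizes: the neutrality-slope recovery uses 200
  sequences of 3000 codons (matching the cohort scale the package
  targets); the RCDI lower-bound check brute-forces 10,000 random count
  tables; host-ranking recovery uses 100 replicates of 3-sequence
  cohorts against 4-host panels, requiring the generating host to win on
  CAI, RCDI and SiD simultaneously in at least 95% of replicates.

## Limitations

The package does not screen recombination, build phylogenies, model
PIPO's frameshift (PIPO is treated as a supplied pre-extracted CDS), or
test group differences of the adaptation indices; ENC variants
(ENC-prime), codon-pair and dinucleotide statistics, and tAI are out of
scope. CAI/RCDI values depend on the host reference build — comparisons
across studies require the same reference CDS sets, which is exactly why
the reference construction is explicit and reproducible here.

## A compact end-to-end run

```{r example}
cohort <- simulate_cohort(12, 400, regime = "selection", beta = 1, seed = 7)
res <- run_codon_analysis(cohort)
res
glance(res$neutrality)
head(tidy(res$pca)[, 1:3])
```
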