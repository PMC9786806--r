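---
title: "Inferring plant reproduction pathways from the flow cytometric seed screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring plant reproduction pathways from the flow cytometric seed screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The measurement and the inference problem

Angiosperm seeds contain two genetically informative tissues. The embryo
derives from the egg cell; the endosperm derives from the central cell of
the embryo sac, normally fertilized alongside the egg. In sexual
reproduction a reduced (haploid-phase) embryo sac is double-fertilized:
for a mother of ploidy $m$, embryo $= m/2 + m/2 = m$ and endosperm
$= 2\cdot m/2 + m/2 = 3m/2$. Gametophytic apomixis changes each component
independently: the sac may arise unreduced (apomeiosis), the egg may
develop without fertilization (parthenogenesis), and the central cell may
still require fertilization for the seed to develop (pseudogamy) or,
rarely, develop autonomously. Because every deviation shifts the
embryo/endosperm DNA contents in a characteristic way, measuring both
tissues of single seeds by flow cytometry — the flow cytometric seed
screen, FCSS — identifies the pathway of each seed.

`seedscreen` implements the full chain: peak quantities → 2C values →
ploidy categories → per-seed pathway explanations → per-tree and
per-cytotype summaries → multivariate grouping of mother trees, plus a
synthetic-data generator with hidden ground truth.

## Genome size and ploidy calling

2C DNA amounts follow the internal-standard ratio formula
$2C_{sample} = 2C_{IRS}\cdot(\text{peak}_{sample}/\text{peak}_{IRS})$,
which is invariant to channel gain. Two standards are built in (*Pisum
sativum* cv. Ctirad, 9.09 pg; *Solanum pseudocapsicum*, 2.59 pg). QC is
deliberately annotation-only: embryo/standard/maternal peaks fail above
6% CV, endosperm above 9% (both strict — a boundary CV passes), and
embryo peaks need at least 1300 nuclei. These are the screen's
conventional thresholds; all are configurable in `qc_thresholds()`.

Mature plants are called from empirical per-cytotype 2C intervals
(defaults 1.37–1.67 pg for 2x up to 3.42–4.18 pg for 5x). The intervals
are deliberately non-exhaustive: a 2C value in a gap is reported as
`unclassified` with the two nearest candidates, never silently rounded.

Seed tissues are called on ratios, not picograms: embryo level
$= m \cdot (\text{peak}_{emb}/\text{peak}_{ref})$ against a reference of
known ploidy, endosperm against the called embryo. Working within one
measurement cancels accession-level genome-size variation (triploid
accessions differ measurably in monoploid genome size, so a pg-based
endosperm call would inherit that variance twice). Raw levels snap to a
0.5x grid spanning 1x–20x with half-width 0.25: the published categories
are exactly this grid (3x, ~3.5x, …, ~19.5x), integral levels are
euploid, half levels aneuploid "approximate" categories, and everything
above 12x carries an `uncertain` flag because identification error grows
with ploidy — such seeds stay in tabulations but are excluded from
sperm-reconstruction confidence statements.

## The pathway engine

For observed grid levels (maternal $m$, embryo $E$, endosperm $D$) the
engine enumerates the full scenario space

* sac reduction: reduced ($m/2$) or unreduced ($m$), optionally
  endoreplicated at the sac level (doubling egg and central cell — needed
  for, e.g., a 6x embryo with ≥14x endosperm on a 3x mother);
* egg fate: parthenogenetic, or fertilized by exactly one sperm;
* central cell: binucleate ($2\times$egg) or trinucleate ($3\times$egg);
* 0–2 sperm into the central cell, drawn (with repetition) from the
  candidate set, default $\{1, 1.5, 2, 2.5, 3, 4\}$x;
* optional endosperm endoreplication (doubling after fertilization);

and keeps scenarios satisfying both conservation equations within a
tolerance of 0.25x (half the grid step, so grid inputs match exactly; raw
unsnapped levels may be matched with a looser tolerance). One structural
constraint is imposed: a fertilized egg implies a fertilized central cell,
because the fertilizing pollen tube delivers a sibling sperm. Without it,
arithmetically vacuous scenarios appear (e.g. a "sexual seed with
autonomous endosperm" explaining embryo = endosperm = $m$), which the
screen's interpretive tradition rejects; it also makes the triple
$(2x, 2x, 2x)$ correctly unresolvable.

### Ranking and ties

Admissible scenarios are ranked by a lexicographic cost, most significant
first:

1. **apomictic components in a diploid mother** — unreduced sacs and
   parthenogenesis are effectively absent from diploid hawthorns, so for
   $m \le 2$ each such component is penalized ahead of everything else.
   This is a biological prior, not arithmetic: without it no ordering can
   simultaneously prefer sexual + endoreplication for a diploid
   2x$_{emb}$/6x$_{end}$ seed and parthenogenesis over sexual +
   endoreplication for a tetraploid 4x$_{emb}$/12x$_{end}$ seed;
2. **unreduced-like sperm count** — sperm in the declared unreduced set
   (default 3x, 4x) or at/above the maternal level. The relative clause
   matters: a 2x sperm is routine pollen for a triploid or tetraploid
   mother but requires unreduced pollen (or a tetraploid donor) for a
   diploid mother;
3. **aneuploid sperm count** (~1.5x, ~2.5x) — unbalanced reduced pollen is
   real but less plausible than euploid pollen;
4. **endoreplication events** (sac- or endosperm-level);
5. **trinucleate central cell**.

The number of central-cell sperm deliberately does *not* enter the rank:
two-sperm fertilization is the commoner route, so $|n_{sperm}-2|$ orders
the presentation *within* a rank, but compositions like $1x+1x$ versus
$2x$ for an 8x endosperm remain genuine ties, exactly as the source
tables print them ("+ 1x + 1x or 2x"). All co-optimal scenarios are
returned; `classify_seeds()` reports the tie count, flags polyspermy when
*any* co-optimal scenario needs more than two sperm, and reports the
2m:1p balance when *all* co-optimal scenarios carry it. Ordering is fully
deterministic (final tie-break on a canonical scenario encoding string).

### Questionable classes

Three classes are flagged because measurement error cannot be excluded:
endosperm one half-step below twice the maternal level with a
maternal-level embryo (e.g. 3x/~5.5x, nearly the unreduced 6x) — excluded
from meiosis, egg-fertilization and pseudogamy numerators; an aneuploid
embryo half a step above the maternal level with ≥ $3m$ endosperm
(~3.5x/9x–12x) — treated as a mismeasured unreduced parthenogenetic seed
in the rate computations; and the putative >12x endosperm calls, which
stay in every numerator and only lower sperm-reconstruction confidence.

## Summaries and denominators

Screening success is computed over all analyzed seeds; every other rate
uses successfully screened seeds as the denominator. This convention was
fixed by back-calculating the published per-category percentages (e.g.
83/1168 = 7.11%) — percentages use successes, not analyzed counts. One
published cell does not back-calculate (457/1168 = 39.13% against a
printed 38.13%); the package always reports the computed value and the
test suite asserts the discrepancy explicitly rather than encoding the
printed number.

The 2m:1p endosperm-balance share follows the operational band rule: for
an unreduced sac, balanced dose means endosperm $= 3m$ (two maternal
central-cell doses + one paternal dose of $m/2$ sperm… scaled to the
mother), counted within half a grid step ($3m \pm 0.5$) by default because
the neighbouring aneuploid calls are acknowledged as probable measurement
error of the balanced class; `balanced_band = FALSE` restricts to the
exact level. Questionable seeds never enter the balanced numerator.

`fruit_statistics()` covers the reproduction-success side: per-tree
percentages of fruits with 0/1/2+ seeds and the pyrene-count
distribution; trees whose seedless-fruit share exceeds 50% are flagged
putatively seed-sterile (the pattern shown by near-sterile triploids).

## Synthetic data: the stated world

`default_pathway_templates()` encodes, per maternal cytotype, the
published seed-category spectrum as concrete generator scenarios with
probabilities proportional to the published counts (diploids n = 247;
triploids n = 1162 pathway-resolvable seeds; tetraploids n = 110). The two
measurement-error-only classes (aneuploid embryo near the maternal level;
endosperm just under $2m$) are not templates: in the generator's world
those categories arise from noise, not from a pathway. Failure modes are
injected at rates approximating the observed ones (3% missing endosperm
signal, 0.5% multiple signals); measurement CV defaults to 3% per tissue,
a typical good seed histogram (the screen's own QC bounds are 6%/9%).

The noise model is multiplicative Gaussian on the emitted peak *mean*
(sd $= cv/100 \times$ mean), with the CV interpreted as in cytometry
practice. This is a deliberately pessimistic reading — on a real
instrument the peak mean is estimated from ≥1300 nuclei and is far more
precise than the peak width — and it has a quantitative consequence worth
stating: an endosperm at level $L$ called against the embryo peak carries
relative noise $\approx \sqrt{2}\,cv$, so at $cv = 2\%$ an 8x endosperm
has level-noise sd $\approx 0.23$x against a bin half-width of 0.25x.
High-ploidy categories therefore cannot be recovered at ≥99% under this
model, while low-ploidy spectra can (a 3x endosperm: sd $\approx 0.08$x,
error rate ≈ 0.5%). The classification-recovery acceptance check
accordingly uses the pure-sexual diploid profile at cv 2% (≥99% of 10,000
seeds) plus a noise-free run across all cytotypes (100%); the graceful-
degradation check at cv 5% asserts that misbinned/unresolved seeds
increase while euploid B$_{III}$ truths almost never surface as *clean*
parthenogenetic calls — they land in flagged aneuploid bins instead
(silent swaps ≤ 1% in the seeded run).

What the generator does **not** emulate: debris and background continua,
instrument drift, G2 peaks of sample tissues, standard/tissue peak
overlap, within-tree genome-size heterogeneity, and pollen-pool structure.
A green recovery test therefore establishes the correctness of the
binning-and-interpretation chain under honest peak-level noise, not
robustness to histogram pathology.

`make_population()` draws mother trees from cytotype proportions
(multinomial by default; a largest-remainder deterministic mode exists for
exact expected counts) with maternal 2C uniform within the published
cytotype interval.

## Grouping mother trees

The grouping pipeline mirrors standard community-ecology practice.
Categories with fewer than 4 seeds overall are dropped (boundary
inclusive). For hierarchical clustering the count matrix is column-wise
percent-maximum transformed, Bray–Curtis dissimilarity is computed
($d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})$), and Ward's
minimum-variance agglomeration is applied via the Lance–Williams
recurrence in its ward.D2 form (recurrence on squared dissimilarities,
heights square-rooted back). The historical "ward" label is ambiguous
between ward.D and ward.D2; ward.D2 is the variant that actually
implements Ward's criterion on non-squared input and is the package's
choice. Ties in the merge step break deterministically on the smallest
pair of current indices. DCA, by contrast, runs on the raw percentage
matrix (the transform is applied only before clustering).

The DCA is implemented from the algorithm: each axis is extracted by
reciprocal averaging (power iteration of site → species → site weighted
averaging), axes beyond the first are detrended against every previous
axis by subtracting means within 26 equal-width segments at each
iteration, and axis 1 is exactly the first correspondence-analysis axis.
One simplification is made knowingly: Hill's iterative nonlinear
per-segment rescaling is replaced by a single global rescaling to sd
units (the mean within-site dispersion of species scores is set to 1).
Rescaling is monotone along the axis, so axis ordering, site ranking and
the k = 2 grouping — everything the package's tests and downstream use
depend on — are unaffected; reported axis *lengths* are comparable to,
but not numerically identical with, the classical implementation. Axis
sign is fixed by orienting the first row's score non-negative.

Degenerate inputs error informatively (fewer than 3 non-empty rows or
columns, rank < 2); identical row profiles receive identical scores on
the leading axes.

## Numerical choices

* Grid 1x–20x in 0.5x steps, snap half-width 0.25x; matching tolerance
  0.25x so snapped inputs admit exact arithmetic.
* All CV thresholds strict (">" fails, "=" passes); abundance filter and
  range boundaries inclusive.
* Every stage is pure given (inputs, configuration, seed): re-running the
  CLI writes byte-identical CSVs; the enumeration cache is keyed on
  (maternal, sperm set) and classification memoizes distinct triples.
* Percentages are reported on the 0–100 scale throughout.

## Known limitations

* The cost ordering encodes field priors (diploid apomixis absent, euploid
  pollen commoner than aneuploid, unreduced pollen rare). In systems where
  these priors fail (e.g. apomictic diploids), reconfigure the sperm set
  and read the full tie structure rather than the top label.
* FCSS cannot distinguish apospory from diplospory, nor the provenance of
  a 2x sperm (unreduced pollen of a diploid vs reduced pollen of a
  tetraploid); the engine models composition, not provenance.
* The >12x endosperm region is interpreted only putatively; several
  published cells there are explicitly unresolved and the engine's choice
  among trinucleate/endoreplication/unreduced-sperm alternatives for such
  seeds should be read as one admissible explanation, with the full tie
  set in the output.
* Real FCSS group membership of the original twenty triploid trees is not
  reproducible from printed data (the per-tree category matrix was never
  published numerically); the grouping machinery is validated on synthetic
  two-profile populations instead.
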