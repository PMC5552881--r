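---
title: "Scoring competing endogenous RNAs from MRE maps: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring competing endogenous RNAs from MRE maps: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A competing endogenous RNA (ceRNA) de-represses a target gene by soaking up
the miRNAs that would otherwise silence it. Whether a transcript *can* act
as a ceRNA of a given target is, to first order, a property of its sequence:
it must carry response elements (MREs) for the same miRNA families as the
target, and the arrangement of those sites matters — experimentally
effective sponges tend to carry many sites for shared families, packed into
a short stretch of the 3' UTR and spaced fairly regularly rather than piled
on top of each other.

`cernascan` turns these observations into five analytical significance
tests per candidate transcript, with no supervised training step: the set
of validated ceRNAs for any given target is far too small and there are no
validated negatives, so a scoring function built from calibrated p-values
replaces a classifier.

## From sequences to MREs

miRNAs are grouped by their **seed** (mature positions 2–8): identical seed
means identical target sites, so each seed class is one regulatory unit (a
family). For a family seed we match three high-affinity site classes on the
sense strand of the UTR, following the TargetScan conventions:

* **7mer-m8** — reverse complement of positions 2–8;
* **7mer-A1** — reverse complement of positions 2–7 followed by an `A`;
* **8mer** — reverse complement of positions 2–8 followed by an `A`.

When an 8mer matches, the 7mer matches it contains are the same physical
locus, so the scanner reports the single longest class per family and
offset. Different families matching at overlapping offsets each keep their
own site, because all counting downstream is per family. When CLIP peak
intervals are supplied (the recommended mode — AGO-bound regions are the
high-confidence evidence for a functional site), a match is kept only if
its footprint intersects a peak; peak coordinates may be genomic (mapped
through the transcript's exon intervals, strand-aware) or transcript-local,
which lets the whole pipeline run genome-free on synthetic data.

Site start offsets are divided by UTR length, mapping every transcript to
the unit interval. All spatial statistics below live on $[0,1]$, which
makes them invariant to UTR length by construction.

## The five features

Fix a source gene $G$ and a candidate transcript $T$. Let $N$ be the number
of expressed families, $K$ of which regulate $G$; on $T$'s UTR there are
$n_{tot}$ MREs from $n$ distinct families, of which $k_{MRE}$ sites from
$k$ distinct families belong to $G$-regulating families (the *shared*
sites). The shared sites' sorted unit positions are $x_{(1)} \le \dots \le
x_{(m)}$ with gaps $d_i = x_{(i+1)} - x_{(i)}$.

1. **Shared-MRE enrichment** (binomial). Each MRE on $T$ is a Bernoulli
   trial with success probability $p = K/N$, fixed per run; the feature is
   $\Pr(X \ge k_{MRE})$ for $X \sim \mathrm{Bin}(n_{tot}, p)$.
2. **Shared-family enrichment** (hypergeometric).
   $\Pr(X \ge k) = \sum_{i=k}^{\min(K,n)}
   \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$.
3. **Span**. Under uniform placement the span $S = x_{(m)} - x_{(1)}$ of
   $m$ points has the exact CDF
   $\Pr(S \le s_0) = m(1-s_0)s_0^{m-1} + s_0^m$; a small value means the
   shared sites occupy an unusually short stretch.
4. **Successive distances**. The joint probability that every gap is at
   most its observed value,
   $m!\,\prod_j d_j\,\bigl[1 - \tfrac12\sum_i d_i\bigr]$, evaluated in log
   space. The product form is not guaranteed to stay below 1 in all corners
   of its domain, so the result is clamped to $[0,1]$; a zero gap (two
   sites at one offset) gives 0, which the feature assembly floors at
   $10^{-300}$ so logs stay finite.
5. **Evenness**. With $Y_i = (d_i - \tfrac{1}{m+1})^2$, the statistic
   $S_Y = \sum_{i=1}^{m-1} Y_i$ is compared to its independent-spacings
   moments $E[Y] = \tfrac{m}{(m+1)^2(m+2)}$ and
   $\mathrm{Var}(Y) = \tfrac{4m(2m^3+2m^2-3m+3)}{(m+1)^4(m+2)^2(m+3)(m+4)}$
   via $z = \bigl(S_Y - (m-1)E[Y]\bigr)/\sqrt{(m-1)\mathrm{Var}(Y)}$, and
   the lower tail $\Phi(z)$ is returned: regular spacing, the arrangement
   effective sponges favour, yields a small value. We center the *sum* at
   $(m-1)E[Y]$ — the dimensionally consistent reading of the limit — and
   keep the whole statistic in one function so an alternative scaling is a
   one-line change.

Degenerate cases return 1 rather than dropping the candidate: features 3–4
need at least two shared sites and feature 5 at least three, and a
candidate with no shared sites gets $(1,1,1,1,1)$ — uninformative, never
missing, so the score is defined for every candidate.

### Reciprocity, score and empirical p-values

Effective competition is mutual: if $T$ sponges $G$'s miRNAs then $G$
sponges $T$'s. Every feature is therefore recomputed with the roles
flipped — the candidate's regulating families are taken to be every
expressed family with at least one MRE on the candidate, and the five tests
are applied to the *target's* UTR — and multiplied with its forward
counterpart. The final score is

$$s = -\tfrac{1}{5}\sum_{i=1}^{5} \log p_i$$

over the five combined features, and each candidate's empirical p-value is
the fraction of candidates scoring at least as high (ties count as at least
as extreme, so the estimator is never anti-conservative). Predictions are
sorted by score with gene-id tie-breaks, and the upper 98% quantile flag
marks the top 2% of scores (linear-interpolation quantile, `type = 7`).

## Expression filters

Three filters precede scoring, with thresholds exposed as parameters:

* genes below 10 counts **in every sample** are dropped (one adequately
  covered sample suffices to keep a gene);
* miRNAs with mean expression strictly below the 5% quantile of all
  miRNAs' values are treated as not expressed; a family is expressed when
  any member is;
* candidates are kept only within a strict 10-fold window of the target's
  mean expression — crosstalk is expected near equimolar abundance. Means
  across samples are used (the simplest stable summary; a median variant
  would be a one-line change).

The filters act on disjoint criteria and commute; this is asserted by a
regression test.

## The uniform null and its calibration

All three spatial features are calibrated against i.i.d. uniform placement
of sites on $[0,1]$. Two checks support this null and probe its limits:

* `shuffle_utr_check()` shuffles a UTR (mononucleotide shuffle, exact
  composition preserved per replicate), rescans for one site string, and
  KS-tests the pooled normalized match positions against Uniform(0,1). On
  composition-matched random sequence the test is comfortably
  non-significant, as expected for a memoryless placement process.
* Under simulated uniform placement the span feature is **exactly**
  Uniform(0,1) distributed — its CDF is continuous and exact — and the test
  suite pins this with a KS test at $\alpha = 0.01$ on $10^4$ replicates.

The evenness feature is different, and deliberately documented rather than
patched: its normal approximation uses independent-spacings moments, but
uniform spacings are negatively correlated, so the $z$ statistic is
correctly centred yet under-dispersed — in simulation its standard
deviation tends to $\approx 0.71$ rather than 1, with a persistent
right skew. The null distribution of the evenness p-value is therefore
centred (mean $\approx 0.49$) but not exactly uniform: its ECDF stays
within $\approx 0.12$ of the diagonal at $m = 20$ and shrinks only slowly
with $m$. Practically the lower tail is *conservative* (fewer small
p-values than nominal), so evenness never inflates a candidate's score
spuriously; the test suite pins the measured behaviour (mean within
$[0.45, 0.55]$, ECDF deviation below 0.15) instead of asserting a
uniformity the approximation does not deliver.

## The synthetic corpus

`generate_fixture()` builds a complete input bundle from one seed. Its
defaults are the package's standard validation conditions: 200 background
genes plus 3 planted ceRNAs and one target; 50 miRNA families of which 10
regulate the target; UTRs of 1,500–3,000 nt with uniform base composition;
planted ceRNAs carry 8–12 shared-family sites spaced evenly inside a
random window of 0.2 UTR lengths (the clustered-and-regular arrangement
the features are designed to detect), while the target carries one or two
sites of every regulating family and background transcripts carry a
Poisson(4) number of random-family sites at uniform positions. Peaks cover
every planted site (with 5–15 nt jitter) plus up to two random decoy
windows per transcript, mimicking CLIP evidence; expression is log-normal
across background genes with negative-binomial per-sample counts, and
planted ceRNAs are drawn within 2-fold of the target so the fold filter
never removes ground truth — the filters are exercised by the background.

What the generator does **not** emulate: realistic base composition and
its effect on incidental seed matches, isoform structure (one transcript
per gene), CLIP peak-calling noise, and any coupling between expression
level and sponge efficacy — the method scores *potential* ceRNAs from
sequence alone, and so does the fixture. Passing the recovery tests
therefore demonstrates that the statistics detect the planted spatial and
family-sharing structure through the full pipeline, not that the method's
assumptions hold in any particular biological dataset.

Validation problem sizes, chosen to give tight Monte-Carlo error while
keeping the default suite quick: $10^6$ draws per $n$ for the span
closed form (agreement within 3 standard errors over a grid of spans),
$10^5$ draws for the spacing moments, $10^4$ replicates for null
calibration, and 20 independent corpora for planted-ceRNA recovery
(median planted rank $\le 2$; $\ge 90\%$ of planted genes inside the 98%
score quantile; planted scores dominate background by a one-sided
Wilcoxon test).

## Numerical and edge-case choices

* p-values are floored at $10^{-300}$ before any log.
* The distances feature is evaluated as
  $\exp\bigl(\log m! + \sum \log d_j + \log(1 - \tfrac12\sum d_i)\bigr)$ to
  avoid overflow of $m!$ and underflow of the gap product.
* Two shared sites at the same offset give a zero gap and hence a floored
  distances feature; sites are counted per match (one MRE per offset), so
  repeated sites under one peak each count.
* Scanning is deterministic and independent of input row order; ties in
  output ordering are broken by (transcript, position, family, class).
* `"upper 98% quantile"` is read as the top 2% of scores; the cutoff value
  itself is a parameter.
* Per-gene reporting keeps the best-scoring isoform by default
  (`isoform_mode = "all"` reports every transcript).

## Limitations

The score weights the five features equally; no attempt is made to learn
weights, for the same reason no classifier is trained. The hypergeometric
and binomial features share information (shared families vs shared sites)
and the three spatial features are computed from the same positions, so
the combined score's null distribution is not analytic — hence empirical
p-values over the candidate set rather than a parametric tail. Candidates
whose UTRs carry no MRE of any expressed family never enter the table (they
have nothing to scan), and candidates with no *shared* sites receive the
uninformative score 0 and tie at empirical p = 1.
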