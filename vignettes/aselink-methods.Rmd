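---
title: "aselink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aselink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model implemented by `aselink`,
the rationale for every default, and the design of the synthetic cohort
generator used for evaluation. Code chunks are illustrative and not
evaluated at build time; the same computations run in the test suite and
in `scripts/acceptance.R`.

## 1. The information leak

A gene is reported as allele-specifically expressed (ASE) in an
individual only when the two parental copies of the gene can be told
apart in RNA-seq reads — that is, only when the individual is
**heterozygous at some exonic SNP of the gene**. A published ASE gene
list therefore certifies, gene by gene, the existence of exonic
heterozygous sites in its anonymous donor. Heterozygosity at rare
variants is itself rare in a panel, so a handful of rare-variant genes
pins the donor down quickly.

## 2. Candidate compilation

Inputs: a gene list, an exon annotation (GTF; exons are grouped by
`gene_name` and their per-gene union is indexed), and a multi-sample
genotype panel (VCF; each alternative allele of each site becomes one
SNP record coded 0/1/2/NA per sample).

For each SNP record $t$ the **heterozygous genotyping frequency** is

$$ f(t) = \frac{\#\{i : g_{ti} = 1\}}{N}, $$

with missing calls kept in the denominator $N$ (a missing call is
evidence of nothing, but the panel size is the reference population).

The candidate set $S_\text{can}$ is every panel SNP overlapping an exon
of a listed gene that passes the frequency filter. The default filter
**removes the open interval** $0.1 < f < 0.5$ and always removes
$f = 0$:

* mid-frequency heterozygotes are shared by much of the panel and carry
  little identifying information, while mildly inflating false matches;
* very common heterozygosity ($f \ge 0.5$) is retained: it contributes
  little weight but does no harm;
* $f = 0$ sites can never be matched and would make the weight
  $-\log_2 f$ infinite.

Both bounds are configurable, and `mode = "keep-range"` inverts the
rule for sensitivity analyses. Boundary values are retained (strict
inequalities define the removed region).

## 3. Linking score

Each panel individual $i$ is scored by the total self-information of
the candidate SNPs at which they are heterozygous:

$$ L(i, S_\text{can}) = \sum_{t \in S_\text{can}:\, g_{ti}=1} -\log_2 f(t). $$

**Sign convention.** Self-information $-\log_2 f$ is used as the weight,
so rarer matched SNPs contribute *more* bits and scores are sums of
non-negative quantities. (The reciprocal form $1/\log_2 f$ is negative
and unbounded for $f < 1$ and cannot serve as an additive evidence
weight; the implemented convention makes rare matches count most, which
is the stated intent of the weighting.)

Auxiliary quasi-identifiers are extra matchable items: knowing the donor
is female adds $-\log_2 f_\text{F}$ bits to every female panel member,
where $f_\text{F}$ is the fraction of females in the panel — exactly
1 bit in a balanced panel (acceptance criterion 1). Ancestry works the
same way over the five categories EUR/AFR/AMR/EAS/SAS.

Ties in $L$ are broken lexicographically by sample id so rankings are
deterministic.

```{r}
can <- compileCandidates(geneList, index, panel)
res <- rankIndividuals(can, panel)
bestMatch(res)
```

## 4. Confidence: gap statistic and entropy probabilities

**Gap.** The ratio of the best to the second-best score. Conventions:
all-zero scores give gap 1 (nothing stands out), a positive leader over
a zero runner-up gives `Inf`. Significance comes from a permutation
null: `nPerm` random candidate sets of the observed size are drawn
uniformly without replacement from the filter-admissible panel SNPs
(genome-wide by default; `pool = "exonic"` restricts to annotated
exons), each is scored, and the add-one empirical p-value is

$$ p_\text{gap} = \frac{1 + \#\{b : \text{gap}_b \ge \text{gap}_\text{obs}\}}{1 + n_\text{perm}}. $$

The add-one form keeps $p > 0$, is exact under exchangeability, and is
uniform under the null — verified by a Kolmogorov–Smirnov test across
200 seeded replicates in the acceptance suite. Auxiliary features of
the observed set are attached unchanged to every null set so the null
matches the observed scoring rule.

**Entropy probabilities.** Scores are mapped to a distribution
$\pi(i) \propto \exp(L_i/\sigma)$, with $\sigma$ the *population*
standard deviation of the scores. Numerically this is computed with
max-shifted exponentials, so it cannot overflow; $\sigma = 0$ (all
scores equal) yields the uniform distribution by continuity. The map is
rank-preserving and invariant to shifting all scores by a constant
(acceptance criterion 5).

## 5. Scenario 2: genome → list

`linkGenomeToLists()` reverses the attack: a known genome is scored
against every anonymized list's candidate set, and lists are ranked.
The (genome, list) score is identical to scenario 1, so no new
machinery is needed; the permutation null permutes over the list axis.
Lists that fail to compile (no annotated gene, or empty after
filtering) score zero with a warning rather than aborting the run.

## 6. Risk analysis and sanitization

`genePrevalence()` computes, per gene, the fraction $p_g$ of lists
containing it and its self-information $-\log_2 p_g$ — strictly
decreasing in prevalence (acceptance criterion 6). `sanitizeList()`
removes a fixed gene set (e.g. the `topCommonGenes()` of the cohort) or
all `HLA-` prefixed genes; removal can only shrink candidate sets, and
emptying a list entirely is an error rather than silent deletion.

`evaluateCohort()` runs the full attack over a cohort and reports
rank-1 accuracy, the top-$k$ accuracy curve (non-decreasing, equal to 1
at $k = N$), and — **as documented approximations**, since the original
definitions are not available — precision as the fraction of correct
identifications among the significant ones ($p_\text{gap} < \alpha$)
and false-positive rate as the fraction of wrong identifications that
are nevertheless significant.

## 7. Synthetic cohort generator

`generateCohort()` produces a fully specified cohort — VCF, GTF,
metadata, per-individual ASE gene lists, and a truth file — with the
single structural constraint that defines the problem: **every gene on
an individual's list has at least one exonic heterozygous SNP in that
individual's genotypes.** Gene lists are sampled only from the owner's
*eligible* genes (those containing an exonic het), with bounded
resampling (`maxRetries`) and a hard error when the demand is
infeasible, never by silently editing genotypes.

**Where the signal comes from.** The attack succeeds exactly to the
extent that gene eligibility separates individuals. If a gene is
eligible for an individual with probability $P$, then listing it
multiplies the posterior odds of ownership by roughly $(1-P)/P$. Panels
dense in *common* exonic SNPs make every gene eligible for everyone
($P \to 1$) and destroy the signal regardless of scoring; rare exonic
SNPs keep $P$ small and identifying. The generator's defaults were
therefore chosen — before any acceptance test was run, from this power
analysis alone — to give $P \approx 0.25$:

* **frequency spectrum**: 95% rare sites, $f = 0.1 \cdot
  \mathrm{Beta}(2,3)$, and 5% common sites, $f = 0.5 + 0.5 \cdot
  \mathrm{Beta}(2,2)$. The mid-range $(0.1, 0.5)$ is left nearly empty
  so the default filter is almost the identity on synthetic data and
  filter behaviour is tested separately with hand fixtures;
* **geometry**: 3 exons per gene of 150–400 bp, introns of 500–1500 bp,
  intergenic gaps of 1000–3000 bp on one synthetic chromosome; SNP
  positions uniform over the covered span;
* **genotypes**: heterozygous with probability $f$, homozygous-alt with
  probability $\min(0.25 f^2, 1-f)$; 3% of sites are multi-allelic with
  two alternative alleles drawn under a haplotype model (allele
  frequency $q = f/2$ each) so per-site alt copies never exceed two;
* **metadata**: deterministic category counts (half F/half M; ancestry
  proportions EUR .50 / AFR .15 / EAS .15 / AMR .10 / SAS .10) so
  auxiliary weights are exactly reproducible.

Defaults: 200 individuals, 300 genes, 5,000 SNPs, 30 genes per list,
seed 7. All output is plain text and regenerated from code; identical
configurations are byte-identical (acceptance-tested).

## 8. Numerical and engineering choices

* Scores are plain double sums of $-\log_2 f$; with $f \ge 1/N$ each
  term is at most $\log_2 N$ bits, far from overflow.
* Entropy probabilities use max-shifted exponentials (Section 4).
* Genomic intervals are held as 1-based inclusive ranges end to end
  (the native convention of GTF, VCF and `GenomicRanges`), so no
  coordinate arithmetic crosses convention boundaries inside the
  package.
* Candidate compilation uses an interval-tree overlap
  (`findOverlaps`) and is acceptance-tested for exact agreement with a
  brute-force double-loop oracle on 50 random instances.
* Per-list permutation seeds in `evaluateCohort()` derive
  deterministically from the user seed, so whole-cohort evaluations are
  reproducible.
* The CLI (`aselink` script, or `runAselink()` in R) distinguishes
  usage errors (exit 2) from data errors (exit 1) and writes a
  `provenance.json` with inputs, parameters, seed and version for every
  run.

## 9. Problem sizes used in validation

| context | individuals | genes | SNPs | genes/list |
|---|---|---|---|---|
| unit-test cohort | 40 | 150 | 2,500 | 20 |
| acceptance recovery | 200 | 300 | 5,000 | 30 |
| null calibration | 40 | 150 | 2,500 | 40 SNP draws |
| oracle instances | 4–12 | 2–20 | 20–100 | — |

The full test suite runs in about two minutes on one CPU; the
acceptance script in about 80 seconds.

## 10. Limitations

* Real-data headline numbers require the actual reference panel and ASE
  call sets; this package validates the *properties* of the method on
  synthetic data and accepts real files of the same formats.
* Precision and false-positive rate are the documented approximations
  of Section 6, not externally defined quantities.
* Linkage disequilibrium is not modelled: the generator draws sites
  independently and the attack does not impute unobserved markers,
  which in practice would only strengthen it.
* The frequency filter bounds (0.1, 0.5) are exposed but not tuned;
  real panels may warrant different settings.
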