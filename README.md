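# aselink

Linkage-attack auditing for allele-specific expression (ASE) gene lists.

## The problem

Lists of genes showing allele-specific expression are routinely published
as "safe" summary data alongside functional genomics studies. They are
not. A gene can only be called allele-specific in an individual who
carries at least one **heterozygous** SNP in that gene's exons — so a
published ASE gene list leaks a partial heterozygosity profile of its
anonymous donor. Given a reference panel of genotyped individuals (for
example, a 1000 Genomes–style multi-sample VCF), an attacker can score
every panel genome against that profile and re-identify the donor.
`aselink` implements this attack as an auditing tool: it quantifies how
identifying a gene list is, attaches a permutation p-value to each claimed
match, and evaluates mitigation by sanitization.

## The model

For each panel SNP *t*, let *f(t)* be its **heterozygous genotyping
frequency**: the fraction of the *N* panel individuals whose genotype at
*t* is heterozygous for that alternative allele. Given an ASE gene list,
the **candidate set** S_can contains every panel SNP that falls in an
exon of a listed gene and survives the frequency filter (by default the
open interval 0.1 < f < 0.5 is removed, as is f = 0; both bounds are
retained). Each panel individual *i* is scored by the self-information
they match:

    L(i, S_can) = Σ_{t ∈ S_can, i heterozygous at t}  −log2 f(t)

Auxiliary quasi-identifiers (sex, ancestry) add −log2 of the matching
category's panel frequency — exactly 1 bit for a sex present in half the
panel. Individuals are ranked by L; the rank-1 genome is the inferred
donor. Confidence is reported two ways:

* **Gap statistic** — the ratio of the best to the second-best score,
  calibrated against a permutation null of random candidate sets of equal
  size drawn from the filter-admissible SNPs, giving an add-one empirical
  p-value `p_gap`.
* **Entropy probabilities** — π(i) ∝ exp(L_i / σ) with σ the population
  standard deviation of the scores, a normalized match distribution over
  the panel.

The mirror attack (scenario 2) links a *known genome* to a collection of
anonymized, phenotype-bearing gene lists by the same score.

## Worked example

Everything below is synthetic and generated in code; `generateCohort()`
guarantees the structural ASE constraint (every listed gene has at least
one exonic heterozygous SNP in its owner's genome).

```r
library(aselink)

co <- generateCohort(cohortConfig(nIndividuals = 40, nGenes = 150,
                                  nSnps = 2500, genesPerList = 20,
                                  seed = 11, maxRetries = 100))
target <- co$lists[[1]]          # the published ASE gene list under audit
listLabel(target)                # its true (hidden) owner
#> [1] "IND001"

can <- compileCandidates(target, co$index, co$panel)
can
#> CandidateSet 'IND001': 55 candidate SNP(s) from 20 gene(s)
#>   filter: exclude f in (0.1, 0.5), f = 0 dropped

res <- rankIndividuals(can, co$panel)
res
#> LinkResult over 40 individuals
#>   best match: IND001 (L = 46.437 bits, gap = 2.072, p_gap = not assessed)

gapSignificance(can, co$panel, nPerm = 200, seed = 42)$pGap
#> [1] 0.009950249

head(linkTable(res), 3)
#>            id     score  nMatched      rank        pi
#> 1      IND001   46.4369        20         1 0.7143664
#> 2      IND036   22.4122        16         2 0.0262745
#> 3      IND033   21.7473        10         3 0.0239794
```

The true owner is recovered at rank 1 with 46.4 bits, a 2.07× gap over
the runner-up (permutation p ≈ 0.01), and 71% of the entropy-based match
probability. Sanitization is audited with `genePrevalence()`,
`topCommonGenes()` and `sanitizeList()` (common-gene or HLA removal);
cohort-scale accuracy, top-k curves, precision and false-positive rate
come from `evaluateCohort()`.

## Command line

`inst/scripts/aselink` (installed under the package's `scripts/`
directory) exposes the pipeline as subcommands operating on standard
formats — GTF annotation, multi-sample VCF, one-gene-per-line lists:

```
aselink compile      --vcf P.vcf --gtf A.gtf --genes L.txt --out DIR
aselink link         --vcf P.vcf --gtf A.gtf --genes L.txt [--sex F] [--n-perm N]
aselink link-genome  --vcf P.vcf --gtf A.gtf --sample ID --lists DIR
aselink evaluate     --vcf P.vcf --gtf A.gtf --lists DIR [--k-max 20]
aselink sanitize     --genes L.txt [--hla] [--remove-top 20 --lists DIR]
aselink simulate     --n-individuals 200 --n-genes 300 --n-snps 5000 --seed 7
```

Exit codes: 0 success, 1 data error, 2 usage error. Every run writes a
`provenance.json` (inputs, parameters, seed, package version).

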