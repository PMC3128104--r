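# powerrep

Power-based replication enrichment for GWAS summary statistics.

## The problem

A genome-wide association study with a few thousand cases often ends
with no genome-wide significant hit, yet the trait may still be driven
by many common variants of small effect. powerrep tests for that
buried signal without ever calling individual SNPs significant. The
idea: if the effect sizes estimated in a **discovery** study are real,
an independent **test** study should replicate each SNP (P < 0.05) at
a rate equal to the statistical power to detect it. So compute, for
every shared SNP, the power to replicate the discovery effect in the
test sample, and fit one logistic regression genome-wide:

```
Pr(replicated) = logit^-1(b0 + b1 * power)
```

A positive, significant `b1` says replication tracks power — evidence
of a shared true signal. It is a single hypothesis, so no per-SNP
multiple-testing correction applies. Interaction variants of the model
ask *where* the replicable signal lives (near exons?) and whether it
behaves like true signal (same direction of effect in both studies).

For a case-control trait, per-SNP power comes from the noncentral
chi-square distribution of the 1-df allelic test, with noncentrality

    lambda = (p1 - p0)^2 / [ pbar(1-pbar) (1/(2 Nca) + 1/(2 Nco)) ],
    p1 = OR p0 / (1 + p0 (OR - 1)),

where OR and the control minor-allele frequency `p0` come from the
discovery study (rounded to 2 decimals) and the sample sizes from the
test study. For a quantitative trait, power comes from the noncentral
F(1, N-2) with Cohen's `f^2 = R^2/(1-R^2)`,
`R^2 = beta^2 * 2p(1-p) / s^2`.

The package also: quantifies the **excess** of replicating SNPs above
a power threshold over the genome-wide expectation; annotates SNPs by
distance to the nearest exon (BED / refGene input); runs permutation
controls; prunes SNPs to approximate linkage equilibrium; computes
ln(OR)-weighted polygenic scores with Nagelkerke pseudo-R²; and ships
forward genotype–phenotype simulators that generate fully synthetic
discovery/test study pairs with known truth, so every claim the
package makes is checked against data where the answer is known.

## Worked example

A fully synthetic case-control pair: 20,000 SNPs, 30% causal with
log odds ratios ~ N(0, 0.08²), causal SNPs planted near exons,
discovery 1,868/2,938 and test 2,191/1,434 cases/controls.

```r
library(powerrep)
res <- run_synthetic("synthetic-bd", n_snps = 20000, seed = 1)
res$fits$I
#> Replication-enrichment logistic model I (all SNPs, n = 20000)
#>             estimate     se   p_value
#> (Intercept)  -3.0436 0.0365 < 2.2e-16 ***
#> power         3.9396 0.0893 < 2.2e-16 ***
res$excess
#> High-power stratum: 1253 of 20000 SNPs (6.3%); 688 replicated (54.9%)
#> Expected at the overall rate of 11.56%: 144.8; excess: 543.2 (~543)
#> Estimated false fraction among stratum hits: 21%
```

Reading this: replication probability rises steeply with power (the
power coefficient 3.94 is the log-odds increase moving from power 0 to
power 1), and among the 1,253 SNPs with at least 60% power, 688
replicated where 145 would be expected by the genome-wide base rate —
an excess of ~543 SNPs carrying true signal, even though no single SNP
is identified.

Single-SNP power is available directly:

```r
power_binary(1.30, 0.30, n_cases = 2191, n_controls = 1434)
#> [1] 0.9991516
```

With real summary files the flow is:

```r
disc <- read_summary("discovery.tsv", "binary")
test <- read_summary("test.tsv", "binary")
exons <- read_exons_refgene("refGene.txt")
res <- run_pipeline(disc, test, exons,
                    config = run_config(trait_kind = "binary"),
                    out_dir = "run1")
```

See the vignette (`vignettes/power-replication-enrichment.Rmd`) for
the models, the simulators, and the design choices.

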