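# genediverse

Comparative characterization of a focal gene set (for example,
chromatin-modifying "epigenes") against a background set, along the axes
where functional diversity leaves measurable fingerprints:

* **gene structure** — genomic span, transcript length, exon counts and
  first/middle/last exon fractions of the canonical transcript;
* **isoform usage diversity** — tree-weighted within-sample Shannon entropy
  and between-sample Kullback–Leibler divergence of isoform proportions;
* **protein complexes** — distinct complexes, mean complex size, and
  constitutive vs variable binding partners;
* **intrinsically disordered regions** — prevalence, disordered fraction,
  longest merged region;
* **disease phenotypes** — ontology-based mapping of disease terms to major
  body systems and inheritance-mode summaries;
* **expression specificity** — a weighted Tau index on a
  TPM → log10 → median-normalized chain;
* **temporal co-expression** — developmental trajectory clustering per brain
  subregion and cross-subregion metaclustering.

A first-class synthetic-data module generates every input with known ground
truth (planted group shifts, known sample trees, known partner counts and
trajectory classes), so the full pipeline runs and is tested without any
external download.

## The statistics at the core

For a gene with isoform proportions $x_{t,i}$ in sample $t$:

* within-sample entropy $H_t = -\sum_i x_{t,i}\log_2 x_{t,i}$ (bits);
  uniform use of 4 isoforms gives 2 bits, a single isoform gives 0, and
  $2^{H}$ is the effective isoform count;
* between-sample divergence
  $D_t = \sum_{i:\,x_{t,i}>0} x_{t,i}\log_2\!\big(x_{t,i}/q_i\big)$ against
  the weighted mean profile $q_i=\sum_t w_t x_{t,i}/\sum_t w_t$.

Both are averaged with per-sample weights $w_t = w_{t,1}\,w_{t,2}$:
a CLUSTALW-style tree weight ($w(t)=d_{t,p(t)}/v_t+w(p(t))$, leaf weights
rescaled to max 1, down-weighting redundant samples) times a
relative-expression weight (the gene's expression in $t$ relative to its
maximum across samples). Group contrasts use permutation tests that resample
background contrast sets without replacement (reporting floor
$1/n_\mathrm{perm}$, e.g. `p < 1e-5` at 100,000 resamples), two-proportion
chi-square tests, and Bonferroni correction. Expression specificity uses
weighted Tau, $\tau_w=\sum_t w_t(1-\hat x_t)/(\sum_t w_t-1)$ with
$\hat x = x/\max(x)$.

See `vignettes/genediverse-methods.Rmd` for assumptions, tie rules, and
every place where an exact convention had to be chosen.

## Worked example

The KAT6A complex preset — three curated complexes, each with ING5 and
MEAF6, distinguished by the BRPF species:

```r
library(genediverse)
tissue_entropy(c(0.25, 0.25, 0.25, 0.25))
#> [1] 2                                  # bits: 4 equally used isoforms
effective_isoform_count(2.1)
#> [1] 4.287094                           # ~4.3 equally expressed isoforms
variable_partners(kat6a_complex_table(), "KAT6A")
#> $n_variable      [1] 3                 # BRPF1, BRPF2, BRPF3
#> $n_constitutive  [1] 2                 # ING5, MEAF6
mean_complex_size(kat6a_complex_table(), "KAT6A")
#> [1] 4
```

A full synthetic run (300 genes, 8 tissues; the generator's defaults plant
the published group differences):

```r
cfg <- validate_config(list(seed = 1,
  simulate = list(n_genes = 300, n_tissues = 8,
                  group_fractions = c(epigene = 0.3, non_epigene = 0.6,
                                      histone = 0.1)),
  stats = list(n_perm = 1000)))
res <- run_pipeline(cfg)
print(res$summary, digits = 3)
#>                  feature      statistic focal_value contrast_value p_value
#> 1            gene_length geometric_mean    4.07e+04       2.11e+04   0.002
#> 2      transcript_length geometric_mean    1.62e+04       7.45e+03   0.002
#> 3             n_isoforms geometric_mean    8.57e+00       6.40e+00   0.002
#> 4           mean_entropy           mean    2.37e+00       2.08e+00   0.002
#> 5        mean_divergence           mean    9.71e-02       7.41e-02   0.002
#> 6            n_complexes           mean    1.19e+00       1.47e-01   0.002
#> 7    n_variable_partners geometric_mean          NA             NA      NA
#> 8    disordered_fraction           mean    2.79e-01       1.10e-01   0.002
#> 9  max_disordered_length         median    1.29e+02       7.95e+01   0.002
#> 10             n_systems           mean    2.65e+00       2.55e+00   0.388
#> 11                   tau           mean    4.32e-01       4.47e-01   0.140
```

Reading the table: simulated epigenes are ~2x longer genes (geometric mean
40.7 kb vs 21.1 kb), carry more isoforms (8.6 vs 6.4), and have higher
within-tissue entropy — each difference saturating the permutation test at
its floor `p = 2/1000` (two-sided). Rows whose eligible-gene pool is smaller
than the focal set at this scale (here variable partners: few multi-complex
background genes among 300) report `NA` rather than an underpowered test.
The `saturated` column marks p-values reported at the test's floor.

## Command line

```sh
genediverse simulate --seed 1 --n-genes 200 --n-tissues 8 --out sim/
genediverse structure --tsv sim/annotation.tsv --out structure.tsv
genediverse diversity --matrix sim/matrix.tsv --map sim/map.tsv \
                      --tree sim/tree.nwk --out diversity.tsv
genediverse test --features structure.tsv --labels sim/labels.tsv \
                 --feature-col gene_length --focal epigene \
                 --n-perm 100000 --seed 1 --out test.json
genediverse run --config config.json --out results/
```

Subcommands: `simulate`, `structure`, `weights`, `diversity`, `test`,
`complexes`, `disorder`, `phenotype`, `specificity`, `tempclust`, `run`.
Configuration is JSON (see `validate_config`).

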