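# nmfgenex

Metagene extraction from two-condition gene-expression profiles via
Kullback–Leibler nonnegative matrix factorization.

## What problem this solves

Bulk expression studies that compare two clinical conditions — the
motivating design is bone-marrow fibroblasts from patients with MGUS
(monoclonal gammopathy of undetermined significance, the premalignant
state) versus multiple myeloma (MM) — face thousands of genes and a handful
of samples. This package implements an NMF-based pipeline that reduces each
condition's matrix to a few *metagenes*, automatically extracts the genes
that define the most informative metagene of each condition, and compares
the two extracted sets to separate a shared expression program from genes
specific to the malignant condition. It is aimed at computational
biologists who want a reproducible, seeded, fully tested version of this
workflow, with a synthetic ground-truth generator to validate every stage.

## The method

Each nonnegative matrix `X` (genes × samples) is factored as `X ≈ WH`
(`W ≥ 0`, `H ≥ 0`, rank `r ≪ n`) by minimizing the generalized
Kullback–Leibler divergence

    D(X‖WH) = Σᵢⱼ [ Xᵢⱼ ln(Xᵢⱼ/(WH)ᵢⱼ) − Xᵢⱼ + (WH)ᵢⱼ ]

with multiplicative updates and random multi-start. The rank is chosen
empirically by consensus clustering over restarts (cophenetic correlation).
Gene `i` gets an entropy-based score on its loading profile
`p(i,k) = Wᵢₖ/Σₖ Wᵢₖ`:

    score(i) = 1 + (1/log₂ r) Σₖ p(i,k) log₂ p(i,k)  ∈ [0, 1]

and is selected iff `score > median + 3·MAD` of all scores (MAD unscaled)
**and** `maxₖ Wᵢₖ > median(W)`. Each selected gene joins its argmax
metagene; the metagene with the most selected genes is the extracted set.
Post-processing intersects the two conditions' sets, maps probes to
symbols, filters non-informative annotation categories (cDNA clones,
hypothetical proteins, non-human, obsolete probes), deduplicates, and
attaches per-condition medians. A validation stage refits the concatenated
matrix, checks that the common genes are contained in its extraction, and
tests (exact Wilcoxon rank-sum) that the selected metagene's
column-normalized coefficients are higher in the malignant condition.

See the methods vignette (`vignettes/metagene-extraction.Rmd`) for the full
model, parameter meanings, the synthetic world's assumptions, and
limitations.

## Worked example

```r
library(nmfgenex)

study <- generate_two_condition_study(seed = 1)   # 2000 genes, 8 + 10 samples
study
#> planted_study: 2000 genes; MGUS 8 samples (rank 5), MM 10 samples (rank 8)
#>   shared markers 25, MM-specific markers 225, seed 1

fit_mgus <- fit_nmf(study$X_a, rank = 5, n_runs = 10, seed = 42)
fit_mm   <- fit_nmf(study$X_b, rank = 8, n_runs = 10, seed = 43)
fit_mm
#> KL-NMF model: 2000 genes x 10 samples, rank 8
#>   divergence 12026.2 after 2000 iterations (max_iter reached), best of run 8

ext_mgus <- extract_genes(fit_mgus)
ext_mm   <- extract_genes(fit_mm)
ext_mm$sets
#> metagene_sets: 8 metagenes, 468 selected genes
#>   most informative: metagene 8 (250 genes)

report <- compare_conditions(ext_mgus$sets$extracted_set,
                             ext_mm$sets$extracted_set,
                             study$annotation, study$X_a, study$X_b,
                             scores_a = ext_mgus$score_table,
                             scores_b = ext_mm$score_table)
report
#> comparison_report: |A| = 108, |B| = 250
#>   common 26, only A 82, only B 224
#>   common: symbol 14, cdna 7, hypothetical 3, non_human 2, obsolete 0; 14 symbols after dedup
#>   only_a: symbol 41, cdna 29, hypothetical 6, non_human 4, obsolete 2; 41 symbols after dedup
#>   only_b: symbol 105, cdna 80, hypothetical 15, non_human 19, obsolete 5; 105 symbols after dedup

mean(study$shared_markers %in% report$common)
#> [1] 1
```

Reading the output: the MM fit's metagene 8 is the most informative (250
extracted genes — exactly the planted MM activation program). Intersecting
with the MGUS extraction recovers all 25 planted shared-program genes in
`common`; `only_b` holds the MM-specific program. The per-set category
counts are what the annotation filter will drop (only symbol-bearing,
deduplicated genes move on to enrichment tools), mirroring the bookkeeping
a real platform annotation requires. The two fits take roughly a minute
together.

## Command line

Every stage is a subcommand of the installed `exec/nmfgenex` script (or
`run_cli()` from R): `simulate`, `fit`, `survey`, `extract`, `compare`,
`validate`, `qc`. Each writes schema-versioned outputs plus a
`*_run_meta.json` with the full parameter set and seed.

```sh
nmfgenex simulate --out-dir study/ --seed 1
nmfgenex fit --matrix study/condition_b.tsv --rank 8 --out-prefix fits/mm --seed 43
nmfgenex extract --model-prefix fits/mm --out-prefix out/mm
```

A JSON config file (`--config file.json`) can supply any flag's default;
explicit flags win.

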