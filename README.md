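# lnctf

Transcription-factor enrichment for lncRNA gene sets from ChIP-Seq peaks.

## The problem

Expression studies (lncRNA microarrays, RNA-Seq) routinely end with a list of
co-expressed long noncoding RNAs and the question *which transcription
factors regulate this set?* Motif scanning cannot answer it cell-line by
cell-line; ChIP-Seq can. `lnctf` crosses ChIP-Seq peak lists of TF
experiments — each tagged with TF name, cell line, species and dataset ID —
with the promoter windows of an annotated lncRNA universe, and identifies the
TFs whose peaks are statistically over-represented around the input set's
transcription start sites. It also answers the two browse questions: which
lncRNAs does a given TF target, and which TFs target a given lncRNA, per cell
line and window.

It is aimed at regulatory-genomics analysts who have a GTF of lncRNA
annotations (e.g. GENCODE), a directory of ENCODE-style
narrowPeak/broadPeak/BED peak files, and a plain-text list of lncRNA
IDs or names.

## The statistic

A feature is **targeted** by a dataset when ≥ 1 peak overlaps its regulatory
region — a strand-aware TSS window, default −2 kb/+1 kb — by ≥ 1 bp. For each
dataset, with `N` the universe size, `M` the universe members targeted, `n`
the input-set size and `m` the input members targeted, the p-value is the
hypergeometric upper tail

P = Σ_{i=m}^{min(n,M)} C(M,i)·C(N−M,n−i) / C(N,n),

i.e. the chance a random size-`n` set would contain `m` or more targeted
members. P-values are Benjamini–Hochberg adjusted across all datasets of the
run; a dataset with adjusted p ≤ 0.05 is flagged a **common TF** of the input
set. Each row also reports `Expected_H = n·M/N` and the odds ratio
`(m/(n−m)) / (M/(N−M))`. A user-supplied reference set (e.g. all
array-detectable lncRNAs) can replace the full annotation as the background
universe.

## Worked example

The package ships a seeded fixture generator, so a complete run needs no
downloads. Build a toy study — 200 lncRNA genes, four null TF datasets, and
one planted dataset whose peaks hit 80% of a 25-gene foreground — then ask
which TF is a common regulator of that foreground:

```r
library(lnctf)

dir <- tempfile()
spec <- fixture_spec(seed = 42, n_genes = 200, n_null_datasets = 4,
                     peaks_per_dataset = 600,
                     planted = planted_spec(foreground_size = 25))
fx <- generate_fixture(spec, out_dir = dir)

res <- enrich_lncrna_set(gtf = file.path(dir, "annotation.gtf"),
                         manifest = file.path(dir, "manifest.tsv"),
                         input = file.path(dir, "foreground.txt"),
                         window = "2k1k", level = "gene", quiet = TRUE)
res
#> # lnctf enrichment: 5 dataset(s), 25 input features, 1 common TF dataset(s) at BH <= 0.05
#> # A tibble: 5 × 13
#>   species      cell_line tf       dataset_id  bg_h  bg_s  fg_h  fg_s expected_h
#>   <chr>        <chr>     <chr>    <chr>      <int> <int> <int> <int>      <dbl>
#> 1 Homo sapiens K562      TF_PLANT DS_PLANT      34   200    20    25       4.25
#> 2 Homo sapiens GM12878   TF02     DS003        114   200    19    25      14.2
#> 3 Homo sapiens K562      TF02     DS004        128   200    16    25      16
#> 4 Homo sapiens HeLa-S3   TF01     DS002        115   200    14    25      14.4
#> 5 Homo sapiens K562      TF01     DS001        120   200    12    25      15
#> # ℹ 4 more variables: odds_ratio <dbl>, p_value <dbl>, bh_p_value <dbl>,
#> #   is_common_tf <lgl>
```

Reading the top row: of the 200-gene universe the planted TF targets 34
(`bg_h`), and of the 25 input genes it targets 20 (`fg_h`) where only 4.25
were expected — hence the tiny adjusted p-value and the `is_common_tf` flag.
The null TFs target half the universe but hit the input at close to their
expected rates, so they stay unflagged.

```r
glance(res)
#> # A tibble: 1 × 6
#>   n_datasets n_common_tf n_input  bg_s threshold min_bh_p_value
#>        <int>       <int>   <int> <int>     <dbl>          <dbl>
#> 1          5           1      25   200      0.05       1.55e-13
```

`tidy(res)` gives the plain tibble, `autoplot(res)` a −log10 BH-p dot plot,
and `write_enrichment_tsv(res, "out.tsv")` the canonical 13-column TSV
(`Species … Common_TF`). The browse panels are
`lncrnas_targeted_by("TF_PLANT", tm)` and `tfs_targeting("LNCG00001", tm)`
for a target map `tm <- build_target_map(datasets, regions)`.

### Command line

The same pipeline is available as a thin CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lnctf.R", package = "lnctf"))')
Rscript "$CLI" enrich --gtf annotation.gtf --manifest manifest.tsv \
    --input ids.txt --window 2k1k --output result.tsv
Rscript "$CLI" query --gtf annotation.gtf --manifest manifest.tsv --tf TF_PLANT
Rscript "$CLI" make-fixtures --out-dir demo --seed 1 --planted
```

`enrich` accepts `--cell-line`, `--level gene|transcript`, `--reference`,
`--threshold`, a custom `--upstream`/`--downstream` pair, and a `--config`
key=value file whose entries flags override.

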