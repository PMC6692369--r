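# juncture

Junction-centric detection of differential alternative splicing and intron
retention from aligned RNA-seq reads, with branch-site distance analysis and
spliceosomal B-complex span arithmetic — plus a deterministic synthetic-data
generator so every stage runs, and is tested, at desk scale.

`juncture` is aimed at analysts studying perturbations of the splicing
machinery (e.g. knockdown of spliceosomal proteins) in two-condition bulk
RNA-seq, where many splicing changes are novel or aberrant and annotation-free
junction evidence matters.

## The method

**Differential junction usage.** Split reads (CIGAR `N` gaps) are extracted
with status-specific overhang filters (≥3 nt for annotated junctions, ≥6 nt
for novel ones).  Each junction *J* is normalised against its *neighbour
junctions*: junctions of the same gene within 5 kb such that every transcript
containing one fully subsumes the other.  Differential usage is a two-sided
Fisher exact test on

|            | condition A | condition B |
|------------|------------:|------------:|
| junction   | J_A         | J_B         |
| neighbours | N_A         | N_B         |

and junction inclusion is summarised by the percent-spliced-in index over the
boundary-sharing neighbours,

PSI = mean( J / (J_sameStart + J), J / (J_sameEnd + J) ),

dropping a term whose denominator is zero.  A junction is called at
p < 0.001, |ΔPSI| > 0.15 and ≥7 supporting reads in one condition, and is
classified by a greedy boundary-sharing closure into Alt 5'SS, Alt 3'SS,
cassette exon (CEx), complex — or *no competitor*, the signature of a
constitutive intron.

**Intron retention.** An intron is called retained when (i) its exact
junction is differentially used (p < 0.001) *without* any competing junction,
and (ii) its strictly-intronic coverage — counted in `max(2, floor(L/500))`
segments and summarised as the *median* per-segment density ratio against
neighbour introns (robust IR) — changes ≥2-fold with Fisher p < 0.001.

**Branch-site distances.** Retained short introns are compared with a
length-matched background (decile matching, 5× oversampling) in their
5'SS-to-branch-site distances via a two-sided two-sample Kolmogorov–Smirnov
test.  A geometry module does the B-complex bookkeeping: a 17-nt U6/5'SS
helix and a 14-nt U2/BS helix separated by 15 nm (≈21 extended nt) imply a
minimal workable 5'SS–BS span of ≈52 nt.

## Worked example

```r
library(juncture)

cfg <- sim_config(n_genes = 60, seed = 42)   # mixed event templates
res <- run_pipeline(cfg)
res
#> <splice_pipeline> 162 junction(s), 75 differential, 13 retained intron(s) [seed 42]

res$summary
#> # A tibble: 9 × 4
#>   section               label       n   prop
#>   <chr>                 <chr>   <int>  <dbl>
#> 1 event_type            Alt3SS      9 0.196
#> 2 event_type            Alt5SS      9 0.196
#> 3 event_type            CEx        15 0.326
#> 4 event_type            complex     0 0
#> 5 event_type            RI         13 0.283
#> 6 retained_length_class <200       12 0.923
#> 7 retained_length_class 200-1kb     1 0.0769
#> 8 retained_length_class 1-5kb       0 0
#> 9 retained_length_class >5kb        0 0
```

The event-type proportions recover the generator's mix (25% CEx, 15% each
alternative splice-site class, 20% RI), and the retained introns concentrate
in the <200 nt class, where the simulated retention targets live.  Individual
calls carry the full statistics:

```r
dplyr::filter(tidy(res), differential) |>
  dplyr::select(junction_id, category, p_value, psi_A, psi_B, dpsi) |> head(3)
#> # A tibble: 3 × 6
#>   junction_id            category  p_value psi_A psi_B  dpsi
#> 1 chr_g0001:400-2544(+)  CEx      2.08e- 4 0.907 0.632 0.276
#> 2 chr_g0001:400-7015(+)  CEx      4.53e-20 0.189 0.790 0.601
#> 3 chr_g0001:2694-7015(+) CEx      3.64e- 8 0.904 0.578 0.326

dplyr::filter(res$ir, retained) |>
  dplyr::select(intron_id, length, fold_change, p_ir) |> head(3)
#> # A tibble: 3 × 4
#>   intron_id              length fold_change     p_ir
#> 1 chr_g0034:1066-1216(+)    150        4.86 5.57e-14
#> 2 chr_g0034:1516-1946(+)    430        2.20 4.66e- 5
#> 3 chr_g0035:1210-1360(+)    150        3.35 5.77e- 9
```

Here the first junction is a cassette skip/inclusion change with
ΔPSI ≈ 0.28 at p ≈ 2×10⁻⁴, and the first retained intron shows a 4.9-fold
robust-IR increase at p ≈ 6×10⁻¹⁴.  `plot_psi()`, `plot_event_summary()` and
`autoplot()` on a `bs_distance_test` give the standard figures.  Real data
enter through `run_pipeline(list(gtf = ..., sam_a = ..., sam_b = ...,
branch_sites = ...))`.

The geometry arithmetic:

```r
extended_span_nt(geometry_model())        #> 21
min_span_nt(geometry_model())             #> 52
construct_distance(120, 96, c(150, 90, 80, 70))  #> 126 66 56 46
```

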