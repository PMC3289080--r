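# supcorr

Correction of intensity-dependent ion suppression in LC-FTMS peptide
elution profiles, and fold-change significance testing against
intensity-resolved null distributions.

## The problem

Ion intensities measured by Fourier-transform mass spectrometry coupled to
liquid chromatography (LC-FTMS) under-report true abundance, and the loss
grows as the signal weakens. The distortion differs from peptide to
peptide but is shared by the isotope species of one peptide. For label-free
quantification this means the fold-change null distribution — what a truly
unchanged peptide looks like between two runs — widens as intensity drops,
and significance calls made against a single global null are unreliable
exactly where most peptides live.

`supcorr` is for proteomics/metabolomics analysts quantifying label-free
LC-FTMS experiments. It exploits the isotope-ratio constraint: the
elemental composition of a peptide fixes the theoretical intensity ratio
`r = x2/x1` between its first heavy-isotope (13C) and monoisotopic (12C)
elution profiles. Since both observed profiles `y1`, `y2` are attenuated by
the same monotone distortion `g` (with correction `f = g^-1`, identity
above a distortion-free threshold of 1e6 ion counts), departures of the
observed ratio from `r` across the elution peak identify `f`. The package:

1. estimates `f` per correctable peptide by **iterative conditional
   modes** — alternate between the total true ion count `T = f(y1) + f(y2)`
   and the best monotone piecewise-linear (log-log, isotonic) fit to the
   targets `x1* = T/(1+r)`, `x2* = rT/(1+r)` — for pairs whose isotope
   ratio lies in 0.2–0.8 and whose heavy-isotope apex clears the
   threshold;
2. pools the fitted distortions into a **function library** and
   characterises suppression across intensity levels;
3. pushes an **experimental null** (fold changes of suppression-free
   peptides in a 1:1 replicate pair) through the library to **predict the
   null at any intensity level**: `r_ij = area(g_i(a_j * y_p)) /
   area(g_i(y_p))` for resampled null draws `a_j` and a template peak
   `y_p`;
4. assigns each measured fold change a two-sided empirical **P-value**
   against the null of its intensity stratum.

A ground-truthed synthetic generator (Gaussian isotope-pair profiles,
per-peptide power-law distortions, lognormal between-run variation,
minimal mzXML output) makes every step testable without instrument data.

## Worked example

```r
library(supcorr)

## one suppressed peptide with known truth
dist <- make_distortion("power_law", gamma = 1.8)    # g(x) = 1e6*(x/1e6)^1.8
gp <- generate_pair(true_apex = 6e6, r = 0.4, distortion = dist,
                    noise_cv = 0.01, seed = 7)
check_correction_conditions(gp$pair)$reason
#> [1] "ok"
fit <- fit_correction_function(gp$pair)
#> iterations: 11
#> observed  area ratio : 0.3822
#> corrected area ratio : 0.4000  (true r = 0.4)
#> corrected / true monoisotopic area: 0.9959
```

The observed heavy/mono area ratio (0.382) sits below the theoretical 0.4
because the weaker isotope is suppressed more; after correction the ratio
is restored and the recovered abundance is within 0.5% of the generator's
truth.

```r
## a 200-peptide 1:1 replicate pair, end to end
rp  <- generate_run_pair(run_spec(seed = 1))
lib <- build_function_library(c(rp$run1, rp$run2))
lib
#> <function_library> 104 functions (296 pairs skipped)
en  <- experimental_null(rp$run1, rp$run2)
en
#> <null_distribution> experimental, n = 70, sd(log10) = 0.0689
res <- assign_significance(rp$run1, rp$run2, lib, en,
                           analysis_config(n_draws = 500, seed = 1))
head(res[, c("sequence", "correctable", "fold_change", "p_value")], 4)
#>        sequence correctable fold_change p_value
#> 1      EHACNSYK       FALSE       0.851  0.4380
#> 2    AMSMHLTFLK       FALSE       1.472  0.0888
#> 3 FFCMPTADGMMGK       FALSE       0.913  0.6646
#> 4   PGIPGHMGSCK       FALSE       1.090  0.5923
mean(res$p_value < 0.05, na.rm = TRUE)   # type-I error on 1:1 data
#> [1] 0.075
```

Uncorrectable peptides keep their observed abundances and are tested
against the predicted null of their intensity bin; on 1:1 data the
fraction of raw P-values below 0.05 stays near the nominal level.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/supcorr.R", package = "supcorr"))')
Rscript $CLI simulate   --out sim --n 50 --seed 4
Rscript $CLI preprocess --mzxml sim/run1.mzXML --peptides sim/peptides1.tsv --cache c1.rds
Rscript $CLI preprocess --mzxml sim/run2.mzXML --peptides sim/peptides2.tsv --cache c2.rds
Rscript $CLI analyze    --cache1 c1.rds --cache2 c2.rds --out results.tsv --seed 2
```

`preprocess` stores per-peptide XIC pairs, peak intervals and isotope
ratios in an RDS cache keyed by the MD5 checksums of its inputs, so
repeated analyses skip the scan decode. `analyze` writes a six-column TSV
(`sequence`, `abundance_before`, `correctable`, `abundance_after`,
`fold_change`, `p_value`; abundance columns hold the two datasets' values
as a comma-joined pair at 6 significant digits).

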