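# sisterates

Does the number of speakers shape how fast a language's basic vocabulary
changes? `sisterates` implements a phylogenetically controlled test of that
question for people working with cognate-coded wordlists (ABVD/IELex-style
databases or binary NEXUS character matrices) and dated language phylogenies.
It compares *sister pairs* — two languages joined directly at their most
recent common ancestor — so every comparison is an independent natural
experiment and Galton's problem (non-independence by shared descent) does not
arise.

The package covers the whole workflow:

1. **Ingestion** — cognate-coded wordlists (`read_wordlist()`) or binary
   NEXUS matrices (`read_nexus_matrix()`), with the standard exclusions
   (loan words, doubtful/excluded forms, concepts not documented in both
   members).
2. **Pair selection** — cherries with ≥ 80% posterior support from a Newick
   tree (`extract_cherries()`), filtered against metadata and a reference
   taxonomy (`filter_pairs()`).
3. **Counting** — every cognate class of the family is classified for each
   pair (`count_pair()`): a class present in one member and elsewhere in the
   family was *lost* by the other member; a class unique to one member was
   *gained*; shared or jointly absent classes are uninformative.
4. **Inference** — two engines:
   - `fit_poisson_rates()`: event counts are Poisson with rate
     `mu_j * N_i^beta` (population size enters log-log linearly).
     Conditioning member 1's count on the pair total `n_j` removes the
     per-pair nuisance `mu_j` (divergence time, data quantity):
     `X_1j | n_j ~ Binomial(n_j, N_1^beta / (N_1^beta + N_2^beta))`.
     The fit reports the MLE of `beta`, a likelihood-ratio test against
     `beta = 0`, and a deviance-based pseudo-R².
   - `fit_contrast_regression()` after `ww_filter()`: standardized contrasts
     `d = (c_1 - c_2) / ((c_1 + c_2)/2) / sqrt(BL)` regressed on
     `x = (ln N_1 - ln N_2) / sqrt(BL)`, after a Welch–Waxman filter that
     removes pairs too recently diverged for reliable rate contrasts.
5. **Simulation** — `simulate_family()` generates cognate matrices with
   known population-dependent gain/loss dynamics, and
   `recovery_experiment()` quantifies bias, RMSE and test size.

The per-pair gain/loss tables for 81 Austronesian, 14 Indo-European and 58
Bantu sister pairs (counts, speaker populations, branch lengths) ship with
the package: `sister_pair_data("indo_european")`.

## Worked example

The Indo-European loss analysis, end to end:

```r
library(sisterates)

ie <- sister_pair_data("indo_european")   # 14 pairs, 28 rows

fit_poisson_rates(ie, response = "loss")
#> <rate_fit> poisson regression of loss counts on population size
#>   n_pairs = 14, estimate = -0.0950 (SE 0.0269), statistic = 12.824, p = 0.0003421, R2 = 0.2163

flt <- ww_filter(pair_contrasts(ie, response = "loss"))
flt
#> <ww_filter> retained 13 pairs; removed 1 (0 undefined, 1 by iteration; rule one_sided)

fit_contrast_regression(flt)
#> <rate_fit> contrast regression of loss counts on population size
#>   n_pairs = 13, estimate = -0.0838 (SE 0.0528), statistic = 2.518, p = 0.1409, R2 = 0.1123
```

Reading the output: the Poisson exponent −0.095 means the loss rate *falls*
with population size — smaller Indo-European languages lose basic-vocabulary
words faster — and the likelihood-ratio statistic 12.8 (χ², 1 df) makes that
effect strongly significant across the 14 pairs. The contrast engine removes
the one very shallow pair (Upper/Lower Sorbian, whose short branch makes its
contrast unreliable) and finds the same direction of effect (slope −0.084),
no longer significant at the reduced sample size. `tidy()`, `glance()` and
`autoplot()` methods are available on all fitted objects, and
`reproduce(family, analysis, response)` runs any packaged family through
either engine in one call.

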