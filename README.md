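# huculnet

Analysis toolkit for **Hucul horse performance-championship records**. The
Hucul, a primitive Carpathian mountain breed under genetic-resources
conservation, is evaluated in annual national championships that combine an
exterior evaluation (≤ 50 points), the Hucul path obstacle course (≤ 80) and
an endurance rally (≤ 80) with conversion factors 0.8 / 1.25 / 0.75 into a
200-point total and a strict finishing order. `huculnet` answers two
questions breeders ask of such records: *which paternal lines start most
efficiently*, and *how well can finishing positions or coarse performance
classes be predicted from descriptive traits alone* (age, sire line, dam
family, sex, coat, breeder, ownership — no expert marks).

The package provides:

- **Records IO** — validated CSV reading/writing of one-row-per-start tables
  (decimal commas accepted on input), championship scoring arithmetic.
- **Pedigree efficiency statistics** — the start-efficiency coefficient
  *SR = 1/(n·m)* per line and championship (*n* starters from the line, *m*
  the line's credited position) and its mean *ASR* over the *k*
  championships entered, plus age-by-place tables and win fractions by
  trait.
- **Fuzzy labels** — piecewise-linear memberships of the groups
  strong/medium/weak as functions of the finishing position, a partition of
  unity at every position; arg-max decoding with ties toward the stronger
  group.
- **Neural models** — feedforward tanh networks (one or two hidden layers,
  the study topology grids) trained from scratch with the
  Levenberg–Marquardt method `(JᵀJ + λI)δ = Jᵀe` using analytic
  backpropagated Jacobians; leakage-safe categorical encoding; repeated
  3-fold cross-validation with tolerance-banded position accuracy and
  group-classification efficiency.
- **A synthetic championship generator** with planted ability structure
  (line + dam-family + age-curve + per-horse baseline + noise), defaults
  sized to the studied population (184 horses, 374 starts over 2009–2019),
  so every stage can be validated by parameter recovery without
  confidential stud-book data.

## Worked example

```r
library(huculnet)

sim <- simulate_dataset(synthetic_config(seed = 1))
sim$dataset
#> <hucul_dataset> 184 horses, 374 starts, years 2009-2019

line_summary(sim$dataset)[, c("line", "k", "asr", "wins", "win_fraction")]
#> # A tibble: 7 × 5
#>   line         k    asr  wins win_fraction
#>   <chr>    <int>  <dbl> <int>        <dbl>
#> 1 Ousor        7 0.156      1        0.143
#> 2 Gurgul      11 0.126      3        0.273
#> 3 Goral       11 0.0952     5        0.455
#> 4 Hroby       11 0.0516     2        0.182
#> 5 Pietrosu     9 0.0513     0        0
#> 6 Prislop     11 0.0333     0        0
#> 7 Polan       11 0.0195     0        0
```

`k` is the number of championships a line entered, `asr` the mean of its
per-championship SR values, `win_fraction` its victories over championships
entered. Note how ASR rewards lean, efficient participation: Oušor entered
only 7 championships with few starters and tops the ASR ranking even though
Goral collected the most wins. A fuzzy label and a cross-validated
classifier:

```r
membership_vector(8)     # position 8 is half strong, half medium
#> strong medium   weak
#>    0.5    0.5    0.0

crossval(sim$dataset, hidden = c(12, 8), task = "group",
         config = training_config(seed = 1, max_epochs = 100, n_restarts = 2),
         n_repeats = 3)
#> <evaluation_report> task=group, hidden=12&8, 3-fold x 3 repeats, n=374
#>   mean efficiency: 0.5169
#>   mean strong_efficiency: 0.3737
```

Mean efficiency is the share of starts whose predicted group (arg-max of the
three network outputs) matches the group of the actual position;
`strong_efficiency` restricts to actual podium (1–3) finishers. At the
default noise level roughly half the group labels are recovered from traits
alone — well above the 1/3 chance level; on zero-noise planted data the same
pipeline exceeds 0.9 (see the methods vignette for the recovery designs).

A YAML-driven pipeline (`run_pipeline()`) and a thin command-line front end
(`inst/cli/huculnet.R` with `simulate`, `stats` and `run` subcommands) wrap
the same functions.

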