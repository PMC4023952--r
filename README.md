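# lazystat

Simulation and analysis toolkit for the *lazy* (exemplar-sampling) account
of intuitive statistical judgment. It is written for cognitive and
quantitative psychologists who want to exercise, end to end and in silico,
a serial-exposure judgment experiment: people observe a long sequence of
numbers, then report the distribution's shape, central tendency and
variability from memory. The lazy account holds that every observed value
is stored verbatim as an exemplar and that a judgment is computed on a
small random sample (short-term memory sized, k ≈ 4) retrieved at query
time — so judgments should be order-blind, means unbiased, and variability
underestimated. The package lets you generate the constrained stimulus
designs, simulate participants under uniform, recency- or primacy-weighted
retrieval (plus an eager running-estimate comparator), score them, and test
the predictions.

## The core statistic

Knowledge of distribution shape is scored on the ten decile bins of the
1–1000 rating scale with a signed **Shape Index**,

SI = Σᵢ sᵢ (xᵢ − pᵢ),

where xᵢ is the judged proportion in bin i, pᵢ the normative proportion
(0.1 under the uniform design), and sᵢ a sign vector that is +1 on central
bins, −1 on extreme bins and 0 on two excluded, uninformative bins
(301–400 and 801–900 by default). SI = 0 indicates a uniform judgment,
SI > 0 a unimodal-leaning and SI < 0 a bimodal-leaning one:

```r
library(lazystat)
shape_index(rep(0.1, 10))                       # 0
shape_index(beta_decile_probabilities(2.4, 2.4)) # 0.392  (unimodal)
shape_index(beta_decile_probabilities(0.5, 0.5)) # -0.357 (bimodal)
```

Accuracy of mean/median/MAD estimates is scored as signed and absolute
deviation from the normative value (`deviation()`), and the between-subjects
sensitivity of the whole design is quantified with noncentral-F power,
λ = n(k−1)·RMSSE²:

```r
anova_power_between(k_groups = 3, n_per_group = 16, rmsse = 0.5)
#> 0.6864
```

## Worked example

Simulate the repeated-judgment design (exposure interrupted after 60 of
120 values by an intermediate production test; n = 14 per presentation
order) with uniform random retrieval:

```r
cfg <- experiment_config(experiment = 2, scheme = sampling_scheme(), seed = 7)
res <- run_experiment(cfg)
aggregate(si ~ condition + test_time,
          data = subset(res$scored, task == "production" & provenance == "all"),
          FUN = function(x) round(mean(x), 3))
#>   condition    test_time     si
#> 1        BU        final -0.018
#> 2        UB        final -0.014
#> 3        UN        final  0.021
#> 4        BU intermediate -0.425
#> 5        UB intermediate  0.357
#> 6        UN intermediate -0.004
```

The simulants are data-driven but order-blind: at the intermediate test
they report the shape of the half they have seen (unimodal-positive under
U-B, bimodal-negative under B-U, flat under UN), and at the final test all
three conditions converge on the uniform truth. The mixed ANOVA carries
that pattern as a large condition × test-time interaction with no
test-time main effect:

```r
res$analysis$production_by_test_time
#>   effect           F   df1   df2             p
#> 1 between     31.0       2    39 0.00000000860
#> 2 within       0.237     1    39 0.629
#> 3 interaction 29.3       2    39 0.0000000172
```

Because the simulated sampling-task selections depend only on the
remembered profile, matrices built from exposed (old) and withheld (new)
values score alike:

```r
old_new_comparison(res$scored)
#>   provenance mean_si sd_si     n
#> 1 old        -0.0125 0.104    42
#> 2 new        -0.0119 0.113    42
```

Swap `sampling_scheme("recency", decay = 0.5)` into the config to watch
order effects appear: the final-test SI then takes the sign of the
second-presented half. `write_experiment(res, "out/")` saves the stimulus,
response, scored and deviation tables as CSV plus the ANOVA results as
JSON; `read_config()` builds the same configuration from a YAML file.

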