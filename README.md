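# dmces

Outlier detection for circular-circular regression by row deletion.

Many scientific measurements are angles: wind directions, seasonal peaks,
the time of day at which blood pressure peaks (24 h mapped to 360°).  When
one angle is regressed on another, a single aberrant observation can
distort the fitted relationship badly, and ordinary regression
diagnostics do not carry over because angles live on the circle.  `dmces`
implements a complete detection pipeline for the Downs–Mardia
circular-circular regression model: maximum-likelihood fitting, a
residual summary statistic, a row-deletion influence statistic, and the
Monte-Carlo machinery to calibrate its critical values and measure its
power.

## The model and the statistic

The Downs–Mardia model links two angles $u, v \in [0, 2\pi)$ through

$$\tan\tfrac{1}{2}(v - \beta) = \omega \tan\tfrac{1}{2}(u - \alpha),
\qquad \omega \in [-1, 1],$$

with von Mises errors $VM(0, \kappa)$ around the conditional mean
direction $\mu(u) = \beta + 2\arctan\{\omega\tan\tfrac12(u-\alpha)\}$.
The fit maximises the precision $\hat\rho = \tfrac1n \sum_j \cos(v_j -
\hat v_j)$ (equivalently the $\kappa$-profiled likelihood) from an
exhaustive grid start, and $\hat\kappa = A_1^{-1}(\hat\rho)$.

Fit quality is summarised by the mean circular error of the residuals
$d_j \in [0, \pi]$,

$$MCEs = \frac{1}{n} \sum_{j=1}^{n} \sin(d_j / 2) \in [0, 1],$$

and influence by the row-deletion statistic

$$DMCEs = \max_j\, |MCEs - MCEs_{(-j)}|,$$

the largest change in the error summary caused by deleting one
observation (refitting the model on each reduced sample).  An
observation is flagged as an outlier when $DMCEs$ exceeds a cut-off
point — an upper percentile of the statistic simulated under clean data
at the sample's size and error concentration.

## Worked example

The shipped fixture is a synthetic circadian-style dataset: ten
subjects, two systolic blood-pressure peak times each (degrees), with
one subject planted at the anti-mode of its expected position.

```r
library(dmces)
x <- read_angle_table(system.file("extdata", "circadian_synthetic.csv",
                                  package = "dmces"), unit = "degrees")
dm_fit(x)
#> Downs-Mardia circular regression fit
#>   n = 10 observations
#>   alpha = 0.5928 rad (33.97 deg)
#>   beta  = 0.3817 rad (21.87 deg)
#>   omega = 0.6837
#>   rho = 0.7919, kappa = 2.7755, loglik = 7.9252

dmces_detect(x, cutoff = 0.07)
#> DMCEs row-deletion outlier report
#>   n = 10, refit on deletion: TRUE
#>   MCEs (full sample) = 0.1425
#>   DMCEs = 0.0885 at observation 8
#>   cut-off = 0.0700 -> observation 8 flagged as influential
```

Deleting one observation changes the mean circular error by 0.0885 —
far more than any other deletion and above the cut-off — so subject 8
is flagged.  Refitting without it shows how strongly that single point
pulled the estimates: $\hat\rho$ rises from 0.79 to 0.99 and
$\hat\kappa$ from 2.8 to 47.2, i.e. the remaining nine subjects follow
a tight one-to-one relationship that the outlier had been masking.

The same workflow is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dmces", package = "dmces"))')
Rscript "$CLI" detect --unit degrees --cutoff 0.07 --out report.json data.csv
```

`fit`, `cutoff`, `power` and `simulate` subcommands cover the rest of
the pipeline (`Rscript "$CLI" cutoff --n 10,30 --kappa 5,10 --reps 2000
--out cutoffs.csv` simulates a cut-off table; every subcommand logs its
seed and configuration).

Cut-off calibration and power curves from R:

```r
sc <- dm_scheme(n = 30, error_kappa = 10, reps = 2000, seed = 1)
dmces_cutoff_table(sc, levels = c(0.10, 0.05, 0.01))
dmces_power(sc, lambdas = seq(0, 1, 0.2), level = 0.05)
```

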