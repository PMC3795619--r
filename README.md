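# raygrowth

Age-and-growth estimation for data-poor elasmobranch populations.

Growth parameters — the asymptotic size and the rate at which it is
approached — underpin demographic assessments of sharks and rays, yet for
rare or protected species the available size-at-age samples are often
tiny (a few dozen animals) and miss whole age classes. `raygrowth`
implements a multi-stage workflow designed for exactly that situation,
developed around vertebral band-pair ageing of tropical stingrays whose
size metric is disc width (W<sub>D</sub>, cm):

1. **Ford–Walford starting values.** Mean size at age *t*+1 regressed on
   mean size at age *t* gives closed-form starts for the asymptote and
   growth coefficient.
2. **Model comparison by nonlinear least squares + AICc.** Four standard
   growth functions are fitted and ranked by bias-corrected AIC:

   | model | mean disc width at age *t* |
   |---|---|
   | VBGF | W<sub>∞</sub>(1 − e<sup>−k(t−t₀)</sup>) |
   | 2VBGF | W<sub>∞</sub>(1 − b·e<sup>−kt</sup>), b = (W<sub>∞</sub> − W₀)/W<sub>∞</sub> |
   | logistic | W<sub>∞</sub>W₀e<sup>kt</sup> / (W<sub>∞</sub> + W₀(e<sup>kt</sup> − 1)) |
   | Gompertz | W<sub>∞</sub>·exp(ln(W₀/W<sub>∞</sub>)·e<sup>−kt</sup>) |

   The two-parameter von Bertalanffy (2VBGF) fixes the size at birth W₀
   — usually well documented for elasmobranchs — so only W<sub>∞</sub>
   and k are estimated.
3. **Bayesian estimation of the 2VBGF** by Metropolis–Hastings sampling
   under informative priors: W<sub>∞</sub> ~ Lognormal with natural-scale
   mean 77 cm and log-scale sd 0.5; k ~ Beta(21.9, 162.3) per year;
   residual variance ~ Inverse-Gamma(0.01, 0.01). Convergence is checked
   with the Geweke diagnostic.

The package also provides the multi-reader ageing-precision indices
(IAPE and CV), consensus-age and readability-filtering rules, a
synthetic-data generator matching the statistical structure the analysis
assumes, and a simulation study comparing the least-squares and Bayesian
estimators under data-poor sampling designs.

## Worked example

Fit and rank the four growth models on a synthetic cowtail-ray sample,
then re-estimate the 2VBGF in the Bayesian stage:

```r
library(raygrowth)

tpl <- ray_presets()$P_atrus   # generating curve: w_inf = 156 cm, k = 0.16/yr
tpl$n <- 100L
d <- generate_sample(tpl, seed = 7)

cmp <- compare_growth_models(d, w0 = 36.5)
cmp$ranking
#>     model delta_aicc support    aicc    w_inf         k  t0_or_w0      rss   n
#>     vbgf2      0.000 highest 347.303 156.1728 0.1630282 36.500000 3028.135 100
#>      vbgf      1.503 highest 348.806 156.7023 0.1571293 -1.860188 3007.981 100
#>  gompertz      5.788   lower 353.091 154.9658 0.1985029 50.209997 3139.652 100
#>  logistic     12.193   lower 359.496 153.9489 0.2384427 56.538416 3347.331 100
```

The 2VBGF attains ΔAICc = 0 (the VBGF, within 2 units, also has high
support); its least-squares estimates sit close to the generating values.
The Bayesian stage quantifies the uncertainty:

```r
fit <- fit_growth_bayes(d, w0 = 36.5, config = mcmc_preset("desk", seed = 11))
summary(fit)
#> Posterior summary (median with 95% credibility interval)
#>  parameter   median    lower    upper geweke_z converged
#>      w_inf 156.4074 154.2816 158.7539  -1.3636      TRUE
#>          k   0.1616   0.1515   0.1722   1.8452      TRUE
#>     sigma2  31.1293  23.6604  41.6309   0.1256      TRUE
#> acceptance rate: 30.1%
```

The posterior medians (156.4 cm, 0.162/yr) recover the generating
parameters, the 95% credibility intervals bracket them, and |Geweke z|
< 1.96 indicates a converged chain. Ageing precision from a simulated
three-reader matrix:

```r
m <- generate_reader_matrix(rep(2:9, each = 5), epsilon = 0.2, seed = 7)
ageing_precision(m)
#> Ageing precision (n = 29 animals)
#>   IAPE = 4.557%   CV = 6.305%
#>  reader  iape    cv
#>       1 5.155 6.314
#>       2 3.699 4.531
#>       3 4.817 5.899
#> readability counts: 1:13 2:16 3:11
```

A lower IAPE/CV means tighter inter-reader agreement; animals with
readability score 3 (here 11 of 40) are excluded before the indices are
computed. `run_full_workflow()` chains all stages for a CSV input and
writes seed-stamped result tables plus a JSON manifest; `run_comparison()`
reproduces the NLS-vs-Bayes simulation experiment.

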