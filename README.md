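# nbreg — robust net-benefit regression for cost-effectiveness analysis

Patient-level cost-effectiveness analyses increasingly run through
**net-benefit regression (NBR)**: at a willingness-to-pay λ per unit of
effectiveness, each subject's net benefit is

```
nb_i = λ·E_i − C_i
```

and NBR is the linear regression

```
nb_i = β0 + β_T·T_i + β1·x_i1 + … + βs·x_is + ε_i
```

where `T_i` is the 0/1 treatment indicator and `x_ij` are covariates.
The coefficient `β_T` is the covariate-adjusted *incremental net
benefit* (INB); the intervention is cost-effective at λ when `β_T > 0`,
tested one-sided (H0: `β_T ≤ 0`), and `1 − p` is reported as the
probability of cost-effectiveness. Varying λ traces the
cost-effectiveness acceptability curve (CEAC).

Cost data are heavy-tailed: a few catastrophically expensive patients
can drag an ordinary-least-squares NBR toward themselves, bias the INB
and gut the power of the test. `nbreg` fits the same regression with
six estimators — OLS plus five outlier-resistant procedures:

| method | estimator |
|---|---|
| `ols` | ordinary least squares |
| `huber` | Huber M-estimation (k = 1.345, IRLS, MAD scale) |
| `hampel` | Hampel three-part redescending M-estimation (1.7, 3.4, 8.5) |
| `tukey` | Tukey bisquare M-estimation (c = 4.685) |
| `mm` | MM-estimation: 50%-breakdown S-start, fixed S-scale, 95%-efficiency bisquare M-step |
| `lts` | fast least trimmed squares (h = ⌊3n/4⌋, C-step concentration) |

It is written for health economists and biostatisticians analysing
trial or claims data, and for methodologists studying how cost outliers
distort regression-based cost-effectiveness conclusions: the package
ships the full Monte-Carlo harness (data generator + empirical
size/power experiment) for the cost-outlier contamination study.

## Worked example

Simulate a 400-subject two-arm study in which the intervention buys one
unit of effect for 10 extra currency units (so the true INB at λ is
λ − 10), with 10% of costs replaced by gross outliers near 150:

```r
library(nbreg)
cfg <- sim_config(n = 400, outlier_prop = 0.1, scenario = "I", wtp = 12, seed = 2024)
d   <- sim_nbr_data(cfg, seed = 2024)
set.seed(2024)
fit_nbr_table(d, wtp = c(8, 12), methods = c("ols", "huber", "mm", "lts"),
              covariates = "x")
```

```
  wtp method    inb p_one_sided prob_ce_regression outlier_proportion scale
1   8    ols -4.267     0.92657            0.07343                 NA 29.30
2  12    ols -0.346     0.54503            0.45497                 NA 30.53
3   8  huber -1.989     0.99334            0.00666              0.105  7.31
4  12  huber  1.904     0.05599            0.94401              0.105 10.96
5   8     mm -1.503     0.98463            0.01537              0.107  7.34
6  12     mm  2.626     0.00519            0.99481              0.107 10.83
7   8    lts -0.680     0.78698            0.21302              0.250  7.38
8  12    lts  3.666     0.00188            0.99812              0.250 10.87
```

Reading the λ = 12 rows (true INB = 2): OLS, dominated by the 10% cost
outliers, estimates the INB near zero (−0.35) and gives the
intervention only a 45% probability of being cost-effective — the wrong
call. The robust fits recover INB estimates near 2, reject H0 (MM and
LTS at p < 0.01), and flag the contamination: the M/MM weights put
~10.5% of subjects below weight 0.5, exactly the planted fraction,
while LTS reports its fixed 25% trimming share. At λ = 8 (true INB =
−2) every estimator correctly declines to call the intervention
cost-effective. The `scale` column makes the mechanism visible: the
robust residual scale is ~11, the OLS one inflated to ~30 by the
outliers.

The acceptability curve across λ, per method:

```r
cv <- dplyr::bind_rows(
  ceac(d, wtp = seq(0, 20, 2), method = "ols",  covariates = "x"),
  ceac(d, wtp = seq(0, 20, 2), method = "lts",  covariates = "x", seed = 1)
)
autoplot(cv)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/nbreg.R` (`fit`, `ceac`, `simulate` subcommands; CSV in, CSV
out, JSON run manifests).

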