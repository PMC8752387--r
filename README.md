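# ascotcarer

Preference-weight valuation for the **ASCOT-Carer** instrument — the
seven-domain, four-level measure of informal caregivers' social
care-related quality of life. The package is for health economists and
outcomes researchers who need to (a) turn ASCOT-Carer responses into
utilities with the published Japanese value set, or (b) run, study or
extend the valuation methodology itself: profile-case best–worst scaling
(BWS), composite time trade-off (cTTO), mixed-logit estimation, anchoring
and tariff construction.

## The model in brief

A state is a 7-digit string of levels, e.g. `2234134`. In the BWS survey a
respondent sequentially selects the best, worst, second-best and
second-worst domain of a profile; each selection is a logit choice over
the remaining items, with utility

```
U_ij = V_ij + ε_ij,   V = Σ_p β_p X_p + Σ_{p,q} β_pq X_pq
```

(worst-type choices enter with covariates × −1, and level 4 of "space and
time to be yourself" is the zero reference). The seven domain effects
β_p are random across respondents, β_p = β_p^m + β_p^s·η with standard
normal η, estimated by maximum simulated likelihood over scrambled Halton
draws with the respondent as the panel unit. cTTO values states directly:
x/10 for better-than-dead states, y/10 − 1 through the lead-time branch
otherwise. The latent score of a state, BWS_i = Σ_p u(p, q_p), is mapped
to the utility scale by the anchored least-squares line

```
TTO_i = 0.0305 · BWS_i − 0.0695
```

(constrained through the full-health point), and the tariff tabulates
`slope × u(p, q)` per item plus the intercept. A synthetic-respondent
generator with Gumbel choice noise and normal preference heterogeneity
makes every stage testable end to end; the published Japanese coefficient,
TTO and tariff tables ship as plain-text fixtures.

## Worked example

Scoring states with the published tariff:

```r
library(ascotcarer)
fx <- load_fixtures()

score_state("2234134", fx$tariff)
#> 2234134
#>   0.486

score_dataset(c("2234134", "4444444", "1111111"), fx$tariff)
#>     state utility misery
#> 1 2234134   0.486     19
#> 2 4444444   0.022     28
#> 3 1111111   1.000      7
```

`0.486` is the sum of the seven applicable published weights
(0.166 + 0.133 + 0.049 + 0.012 + 0.121 + 0.063 + 0.011) plus the
intercept −0.069. The value set spans 0.02 (worst state, at 2 decimals)
up to exactly 1 for the full-health state, which by convention does not
carry the intercept. The `misery` column is the sum of level digits, a
crude severity index.

Re-deriving the anchor and tariff from the packaged tables:

```r
bws <- latent_score(fx$tto$state, fx$params)
an <- fit_anchor(bws, fx$tto$mean,
                 anchor_point = c(latent_score("1111111", fx$params), 1))
an
#> anchor: TTO = 0.030449 * BWS -0.069472  (anchored, n = 31, R2 = 0.924, RMSE = 0.088)

build_tariff(fx$params, an)
#> ASCOT-Carer tariff (intercept -0.069; full-health state pinned to 1)
#>                                      level1 level2 level3 level4
#> occupation                            0.173  0.166  0.066  0.028
#> control over daily life               0.147  0.133  0.032  0.009
#> looking after yourself                0.163  0.155  0.049  0.020
#> personal safety                       0.131  0.111  0.046  0.012
#> social participation and involvement  0.121  0.103  0.076  0.011
#> space and time to be yourself         0.205  0.194  0.063  0.000
#> feeling supported and encouraged      0.130  0.117  0.064  0.011
```

Simulating a survey and estimating preferences:

```r
cfg <- simulation_config(n_respondents = 120, seed = 2)
cases <- simulate_bws_dataset(cfg, bws_design(seed = 2))
build_design_rows(cases)
#> exploded BWS data: 21120 alternative rows, 3840 cases, 120 respondents

fit <- fit_mixl(cases, n_draws = 100, seed = 2)  # or fit_mnl(cases)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ascotcarer.R` (`score`, `tariff`, `simulate-bws`,
`simulate-tto`, `fit-bws`, `qc-filter`, `reproduce`).

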