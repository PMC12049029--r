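# betaborrow

Bayesian power-prior borrowing for sequential platform trials with a
binary endpoint.

## The problem

Phase II platform trials in rare diseases — the motivating setting is
relapsed/refractory follicular lymphoma — evaluate a sequence of novel
therapies, each against a concurrent control arm of investigator-choice
standard therapy, with complete metabolic response as the primary outcome.
Recruiting a full control arm for every round is infeasible, so later
rounds randomise 1:4 in favour of the experimental arm and recover control
information by *borrowing* earlier rounds' control data through a fixed
power prior: each historical control likelihood is raised to a
prespecified weight $w \in [0,1]$ before entering the prior. For binomial
data with a Beta initial prior this yields weighted pseudo-counts,

$$p_c \sim \mathrm{Beta}\Bigl(1 + \sum_i w_i s_i,\; 1 + \sum_i w_i (n_i - s_i)\Bigr),$$

and the round's experimental arm is declared a success when

$$\Pr(p_e - p_c \ge 0.15 \mid \text{data}) \ge 0.60 .$$

`betaborrow` provides the conjugate Beta-Binomial analysis with borrowing
(`round_analysis()`), the posterior tail probability by quadrature
(`prob_diff_at_least()`), operating characteristics of the decision rule
by Monte-Carlo simulation (`simulate_oc()`) and exact outcome-grid
enumeration (`exact_oc()`), scenario grids (`build_scenario_grid()`),
effective-sample-size accounting (`effective_sample_size()`),
borrowing-weight sensitivity tables (`weight_sensitivity()`),
control-drift reports for data monitoring committees (`drift_report()`),
synthetic patient-level data (`generate_trial_data()`), and a command-line
interface (`inst/cli/betaborrow.R`). The default `three_round_design()`
encodes the 284-patient layout: 63 + 63 (1:1) in Round 1, then twice
16 + 63 (1:4) borrowing earlier control arms at weight 0.75.

## Worked example

Round 2 analysis: 7/16 concurrent controls and 41/63 experimental
responders, borrowing Round 1's 26/63 controls at weight 0.75.

```r
library(betaborrow)
fit <- round_analysis(binom_outcome(7, 16), binom_outcome(41, 63),
                      history = list(weighted_outcome(26, 0.75, total = 63)))
summary(fit)
#> Beta-Binomial round analysis with power-prior borrowing
#>
#> Control:      7/16 observed; posterior Beta(27.5, 37.75), mean 0.421
#> Experimental: 41/63 observed; posterior Beta(42, 23), mean 0.646
#>
#> P(p_e - p_c >= 0.15) = 0.811  =>  SUCCESS (threshold 0.6)
#>
#> 95% credible intervals (equal-tailed):
#>   control      [0.305, 0.542]
#>   experimental [0.527, 0.757]
#>
#> Borrowed control data:
#>   26/63 at weight 0.75
#> Effective sample size: 63.25 (63 patients to the nearest patient)
```

The posterior probability 0.811 clears the 0.60 certainty threshold, so
this round would be declared successful; the 16 concurrent controls carry
the information of 63.25 effective patients once 63 historical controls
are borrowed at 0.75.

Operating characteristics of that round at true rates 40% (control) vs
65% (experimental), historical data fixed at its 40% realisation:

```r
d <- three_round_design()
exact_oc(scenario(d$R2, 0.40, 0.65, historical_rates = 0.40))
#> P(declare success) = 0.8292  (exact enumeration)
```

i.e. an 83% chance of correctly declaring success when the true
improvement is 25 points. The predefined sensitivity reanalysis across
borrowing weights:

```r
weight_sensitivity(binom_outcome(7, 16), binom_outcome(41, 63),
                   history = list(binom_outcome(26, 63)),
                   weights = c(0, 0.5, 0.75, 1))
#>  weight prior_alpha prior_beta post_alpha post_beta mean_control ...   prob success ess_control
#>    0.00         1.0       1.00        8.0     10.00       0.4444 ... 0.6575    TRUE       16.00
#>    0.50        14.0      19.50       21.0     28.50       0.4242 ... 0.7853    TRUE       47.50
#>    0.75        20.5      28.75       27.5     37.75       0.4215 ... 0.8114    TRUE       63.25
#>    1.00        27.0      38.00       34.0     47.00       0.4198 ... 0.8291    TRUE       79.00
```

The weight-0 row is exactly the no-borrowing analysis and the weight-1 row
exactly the pooled one; the success call is stable across the whole grid
here.

The same operations are scriptable: see `?cli_main` for the `oc`,
`analyze`, `ess`, `sensitivity`, `drift` and `simulate-data` subcommands,
and `inst/extdata/trial_design.yaml` for the packaged design
configuration.

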