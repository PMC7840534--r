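# pollselect

Partition pollinator-mediated phenotypic selection on floral traits among
co-occurring bee species.

## The problem

Plants in natural populations are usually visited by several pollinator
species that differ in abundance and efficiency. Classical phenotypic
selection analysis regresses a plant's relative fitness on its standardized
traits and so measures the *combined* selection by all agents. `pollselect`
implements a partitioning approach for tripping-pollinated systems such as
alfalfa: each plant's seed set is attributed to the bee species that
visited it, in proportion to the flowers each species visited — or to the
flowers each species *tripped*, weighting visits by species-specific
tripping rates (a flower sets seed only after a visitor mechanically
releases its staminal column). Relative fitness `w = y / mean(y)` is then
computed within every species on the *same* plants, and selection is
estimated per species, per attribution basis, and overall:

- directional selection differential `S_j`: slope of `w` on the
  variance-standardized trait `z_j` (equals `cov(w, z_j)`);
- directional gradient `beta_j`: partial coefficient of the multiple
  regression on all traits (direct selection);
- quadratic `C_jj`, `gamma_jj` (reported as twice the raw quadratic
  coefficient; stabilizing < 0, disruptive > 0) and correlational
  `gamma_jk` from the full second-order model;
- opportunity for selection `I = var(w)`;
- distributional selection differential `DSD`: the 1-D transport distance
  between the trait distribution and its fitness-weighted counterpart,
  decomposed as `DSD = dD + dN` (mean shift + shape change), with
  permutation p-values.

Inference combines log-fitness-model t-tests with case-resampling
bootstrap percentile CIs (re-relativized and re-standardized within every
replicate). A calibrated synthetic-data generator — truncated-normal trait
marginals moment-matched to published field summaries, Poisson visitation
with log-linear trait preferences, negative-binomial seed noise through
species tripping rates — provides populations with known ground truth for
validation and power analysis.

## Worked example

Simulate a 153-plant population in which all three bee species prefer
plants with more stems (preference 0.6 per trait SD), then ask each
species' analysis whether it detects that selection:

```r
library(pollselect)
rates <- c(bumble = 0.55, honey = 0.25, leafcutting = 0.80)
sim <- simulate_study(n_plants = 153,
  preference = preference_model(linear = list(
    bumble = c(stems_per_plant = 0.6), honey = c(stems_per_plant = 0.6),
    leafcutting = c(stems_per_plant = 0.6))),
  seed = 42)

rep <- selection_report(sim$plants, sim$visits, rates,
                        settings = bootstrap_settings(B = 1000, seed = 42),
                        bases = c("visited", "total"))
subset(rep, trait_1 == "stems_per_plant" & coefficient_kind %in% c("S", "beta"))
#>      species   basis coefficient_kind estimate p_log_model ci_lower ci_upper significant
#>       bumble visited                S    0.619    2.46e-06    0.374    0.834        TRUE
#>       bumble visited             beta    0.621    3.13e-06    0.376    0.843        TRUE
#>        honey visited                S    0.629    2.43e-06    0.397    0.834        TRUE
#>        honey visited             beta    0.630    2.96e-06    0.400    0.841        TRUE
#>  leafcutting visited                S    0.625    1.78e-08    0.378    0.897        TRUE
#>  leafcutting visited             beta    0.626    2.08e-08    0.361    0.908        TRUE
#>          all   total                S    0.624    2.90e-06    0.392    0.834        TRUE
#>          all   total             beta    0.625    3.60e-06    0.392    0.840        TRUE
```

Every block recovers a directional gradient near the constructed 0.6, with
bootstrap 95% CIs excluding zero. The distributional view agrees — strong
directional change in stems, nothing on a neutral trait:

```r
dd <- dsd_report(sim$plants, sim$visits, rates, bases = "total",
                 B = 1999, seed = 42)
subset(dd, trait %in% c("stems_per_plant", "chroma"))
#>            trait   DSD  p_DSD     dD   p_dD      dN  p_dN
#>  stems_per_plant 0.622 0.0005 0.6195 0.0005 0.00236 0.925
#>           chroma 0.093 0.7415 0.0703 0.5140 0.02270 0.663
```

`DSD = dD + dN` holds exactly; for stems the change is almost purely a
mean shift (`dD` ≈ `S`), and the p-value 0.0005 is the permutation floor
`1/(B+1)`. Opportunity-for-selection values
(`opportunity_for_selection(w)`) in this simulation range from 1.8 overall
to 3.0 for the rare leafcutting bee, whose attributed fitness is the most
zero-inflated.

## Command line

```sh
inst/cli/pollselect all --seed 7 --n-plants 153 --out-dir runs/demo
inst/cli/pollselect select --config config.yaml --bootstrap-reps 2000
```

Subcommands `simulate | attribute | select | dsd | all`; flags override the
YAML config. Artifacts: `plants.csv`, `visits.csv`, `fitness.csv`,
`selection_report.csv`, `dsd_report.csv` and a `manifest.yaml` carrying the
seed and settings needed to regenerate them.

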