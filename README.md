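# rtphazard

Continuous-time hazard curves for non-contact injury after return-to-play
(RTP) in professional football.

After a player returns from injury, the risk of the next non-contact injury
is elevated and decays over the following weeks. Raw injury frequencies
overstate that decay because the number of players still at risk also falls
day by day. `rtphazard` implements the time-to-event answer for analysts of
injury-surveillance data: censored RTP episodes, a daily-resolution
Kaplan–Meier model, and a smoothed continuous hazard curve, together with a
synthetic cohort generator with *known* ground-truth hazard so the whole
pipeline can be validated end to end.

## The method

Each injury record (player, position, injury date, RTP date, contact flag)
becomes the **index injury** of one episode that starts at its RTP date.
The episode ends with the player's next injury if that injury is
non-contact and occurs in the same season (an observed event); otherwise it
is censored at the next contact injury or at the season's last-match date.
From the censored episodes, on a daily grid:

1. **Kaplan–Meier survival**
   S&#770;(t_j) = ∏_{t_i ≤ t_j} (1 − d_i/n_i), with Greenwood variance and
   complementary log-log confidence bands;
2. **cumulative hazard** H&#770;(t_j) = −ln S&#770;(t_j);
3. a **tenth-degree polynomial** is fitted to H&#770; over the first 100
   days (one support point per day, time rescaled to [0, 1] for
   conditioning);
4. the **continuous hazard** is the day-to-day change of the predicted
   cumulative hazard, h(d) = H&#770;_pred(d) − H&#770;_pred(d−1);
5. the **median survival time** is interpolated linearly across the day in
   which S&#770; crosses 0.5.

Curves can be stratified by index-injury severity (minimal 1–3 d, mild
4–7 d, moderate 8–28 d, severe > 28 d of time loss) or playing position.
Three robustness analyses are built in: a baseline comparator re-clocked to
the period after the first 100 post-RTP days, player-level up-/down-sampling
against the over-representation of frequently injured players, and
leave-one-quarter-out round-robin splitting (player level, stratified by
position) against overfitting by the high-degree polynomial.

## Worked example

```r
library(rtphazard)

cfg <- sim_config(rng_seed = 1, n_players = 800)   # four-season synthetic cohort
records <- simulate_cohort(cfg)
analysis <- run_rtp_analysis(records, strata = "severity")
print(analysis)
#> <rtp_analysis>
#>   episodes: 3545 (1226 observed, 2319 censored: 1620 season-end, 699 contact)
#>   median survival: 192.7 days
#>   hazard day 1: 0.00847; plateau: 0.00353; ratio: 2.40; excess half-time: 8 days
#>   strata fitted: severity
```

The cohort yields 3545 RTP episodes; 1226 end in an observed non-contact
same-season injury, the rest are censored at season end or at a contact
injury. The fitted hazard on the first day back is 0.00847 per day, about
2.4 times the late plateau of 0.00353 per day — the pooled curve declines
faster than any single player's hazard because gamma frailty concentrates
early events in injury-prone players. `plot_survival(analysis$km)`,
`plot_risk_set(analysis$km)` and `plot_hazard(analysis$hazard)` draw the
standard figures, and `write_run_outputs(analysis, "results")` writes every
curve as CSV next to the plots with a run manifest.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/rtp-hazard.R simulate --config cfg.yaml --out records.csv
Rscript inst/cli/rtp-hazard.R fit --records records.csv --out-dir results \
    --strata severity --ancillary baseline,roundrobin
```

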