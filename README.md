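# aaades

Individual-level discrete event simulation (DES) of abdominal aortic
aneurysm (AAA) screening, for health economists evaluating screening and
surveillance policy.

Population screening for AAA — a one-off ultrasound invitation at 65 with
surveillance of detected aneurysms and elective repair at 5.5 cm — is one
of the best-evidenced screening programmes, but the questions now asked of
it (different surveillance intervals, lower diagnosis thresholds,
sub-aneurysmal monitoring) are awkward for cohort Markov models, which
need new tunnel states for every interval change. `aaades` instead
simulates event sequences for individuals in continuous time:

* **Growth–rupture model.** Aortic diameter follows a log-linear latent
  trajectory, `d(t) = d0 · exp(g·t)`, with the slope drawn per individual
  conditional on baseline band (zero below 2.0 cm). Rupture is a
  diameter-dependent hazard `h(d) = exp(α + β(d − d_ref))`; rupture times
  are drawn by inverse transform of the cumulative hazard along the
  trajectory (exponential-integral closed form). Scans observe the true
  diameter plus fresh modality-specific error; CT adds a +0.24 cm offset.
* **Event-scheduling engine.** Each individual has a future event list
  (invitation, scans, incidental detection, consultation 71 d after
  referral, surgery 59 d later, rupture, deaths, censoring) popped in time
  order with deaths-first tie-breaks.
* **Twin pairs.** Individuals are simulated in invited/non-invited pairs
  sharing latent trajectory, death and rupture times, and surgical
  indicators (common random numbers), so incremental costs and QALYs are
  estimated with small Monte Carlo error; per-pair RNG substreams make
  results independent of worker count.
* **Economics.** Costs attach to events and are discounted at exact event
  times, `(1+r)^(−t)`; life-years and age-utility-weighted QALYs accrue by
  exact integration. ICER with dominance classification, INMB, CEAC.
* **Oversampling + PSA.** Aneurysmal baselines are oversampled and
  reweighted (Horvitz–Thompson); probabilistic sensitivity analysis draws
  the global uncertain parameters per iteration.
* **Declarative policies.** A policy is a list of diameter cut-points and
  per-band rescan intervals; the current programme, a lengthened-interval
  scenario, and a sub-aneurysmal (2.5 cm) scenario are built in.

All epidemiology and economics live in YAML parameter bundles with
per-value provenance notes; two documented bundles ship with the package
(`mass-validation`, a 4-y trial-era validation configuration, and
`naaasp-basecase`, a contemporary 30-y base case).

## Worked example

```r
library(aaades)

bundle <- builtin_bundle("naaasp-basecase")
draw   <- fix_bundle_at_means(bundle)        # deterministic base case
run    <- run_main_analysis(10000, draw, bundle, seed = 1)
run
#> <aaa_run> 10000 pairs | bundle: naaasp-basecase | policy: current | seed: 1
#>          arm     cost life_years    qalys
#>      invited 249.1395   13.27894 10.14221
#>  non_invited 189.8147   13.25873 10.12720
#>   delta cost 59.3248 | delta QALYs 0.015008 | delta LY 0.020212
#>   ICER: 3952.75 per unit effect
#>   INMB at lambda=20000: 240.8448
```

Per invited man, screening costs ≈ £59 more than no invitation and buys
≈ 0.015 QALYs over 30 years — about £4,000 per QALY, far below the usual
£20,000 willingness-to-pay, with an INMB of ≈ £241. (Published full-scale
analyses of this programme report ≈ £50, 0.0078 QALYs and ≈ £6,400 per
QALY; the packaged bundle approximates unpublished parameters and a
10,000-pair run carries visible Monte Carlo error.)

Comparing policies under common random numbers:

```r
cmp <- compare_policies(builtin_policy("current"), builtin_policy("scenario2"),
                        20000, draw, bundle, seed = 1)
cmp
#> <policy_comparison> scenario2 vs current
#>   delta cost 17.1327 | delta QALYs 0.001532
#> ICER: 11184.37 per unit effect
#>   INMB at lambda=20000: 13.5041
```

Extending surveillance to sub-aneurysmal aortas (2.5–2.9 cm, 5-y rescans)
costs ≈ £17 more per invitee for ≈ 0.0015 extra QALYs — cost-effective at
£20,000/QALY (positive INMB).

A thin command-line interface wraps the same functions:

```sh
Rscript exec/aaasim simulate --bundle naaasp-basecase --pairs 10000 --seed 1 --out out/
Rscript exec/aaasim compare --baseline current --alternative scenario1 --pairs 20000 --out out/
Rscript exec/aaasim validate --pairs 30000 --out out/      # trial-style tables
Rscript exec/aaasim psa --iterations 100 --pairs 5000 --out out/
```

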