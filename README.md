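# ictalnet

Connectome-based simulation of seizure onset and in-silico epilepsy
surgery.

## What this is for

In drug-resistant temporal lobe epilepsy (TLE), resective surgery helps
only some patients, and predicting who will benefit — and which regions to
remove — is an open problem. `ictalnet` implements a whole-brain
computational approach to that question: each brain region is a bistable
oscillator that can be kicked by noise from a background state into a
high-amplitude seizure-like state, and regions are coupled through the
subject's own structural connectome (streamline counts, fibre-length
conduction delays). How quickly regions "escape" into the seizure state
measures seizure propensity; removing regions in silico and re-simulating
measures the predicted benefit of a surgery.

The package is aimed at computational neuroscientists who want a tested,
reproducible implementation of this model family — the simulator, the
subject-model construction, the virtual resection strategies, and the
cohort statistics — together with a synthetic connectome generator that
stands in for patient data, which cannot be redistributed.

## The model

Each of 82 regions (Desikan–Killiany cortex + 7 subcortical structures
per hemisphere) has a complex state `z_i`:

    dz_i = [ f(z_i) + beta * sum_j M_ji (z_j(t - tau_ij) - z_i) ] dt
           + alpha dw_i
    f(z) = (lambda_i - 1 + i*omega) z + 2 z |z|^2 - z |z|^4

with coupling `M = log S / max log S` from streamline counts `S`, delays
`tau` from mean fibre lengths at 7 m/s, and per-region excitability
`lambda_i = -D_i / psi + 0.5`, where `D_i` scores how far the subject's
regional surface area falls below the control distribution (atrophy ⇒
higher excitability). Defaults: `beta = 0.01`, `alpha = 0.05`,
`omega = 15`, `psi = 15`. A node escapes when `|z| > 1`; a run ends when
three distinct nodes have escaped (seizure spreading) or at the horizon.
Integration is fixed-step Euler–Maruyama; see the methods vignette
(`vignettes/connectome-seizure-model.Rmd`) for why the solver step is a
model-level choice here and how the default `dt = 0.0025` is set.

Three virtual surgeries remove three regions each: random (a node plus
its two strongest above-average neighbours), clinical (hippocampus,
amygdala, parahippocampal gyrus — the amygdalohippocampectomy), and
patient-specific (each patient's three fastest-escaping nodes). Benefit
is the paired percentage increase in third-escape time across matched
noise seeds.

## Worked example

```r
library(ictalnet)

config <- run_config(
  cohort = cohort_spec(n_patients = 10, n_controls = 10, seed = 1,
                       atrophy_effect_sd = 2),
  n_iterations = 50,
  strategies = "patient_specific",
  base_seed = 100101
)
val <- run_validation(config)
subset(val$group_comparison, k == 3)
#>  k U         z            p patient_mean patient_se control_mean control_se
#>  3 0 -3.741848 1.082509e-05     18.91062   1.506331     102.8143   11.55498
surg <- run_surgery(config, val)
surg$success_rates
#>          strategy  n n_success success_rate
#>  patient_specific 10        10          100
```

Read: synthetic patients (2 SD of left mesial-temporal atrophy) reach the
three-node seizure criterion after ~19 time units on average, healthy
controls after ~103 (some runs censored at the 200 horizon); U = 0 means
every patient mean is below every control mean, giving the smallest
Mann–Whitney p attainable at n = 10 + 10 (1.1e-5). Removing each
patient's three fastest-escaping regions and re-simulating with the same
noise seeds significantly lengthens escape times in 10/10 patients
(paired t-test, p < 0.05, positive shift).

Lower-level entry points: `generate_cohort()`, `build_subject_model()`,
`simulate_subject()` / `run_iterations()`, `plan_clinical()` /
`plan_random()` / `plan_patient_specific()`, `apply_resection()`,
`network_measures()`, `compare_groups()`, `compare_strategies()`. A CLI
wrapper exists for shell pipelines:

```sh
Rscript -e 'ictalnet::ictalnet_cli()' full-run --patients 4 --controls 4 \
        --iterations 10 --out reports
```

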