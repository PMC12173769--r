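# amyfear

Firing-rate model of amygdala circuitry in fear conditioning, and of how
acute and chronic alcohol exposure reshape it.

Fear conditioning pairs a conditioned stimulus (CS) with an aversive
outcome (US); extinction presents the CS alone until the fear response
fades.  Both processes are implemented by synaptic plasticity of amygdala
inputs.  `amyfear` models five populations — lateral amygdala (LA), basal
fear (BAf) and extinction (BAe) neurons, and mutually inhibiting pro-fear
(CeAOn) and pro-extinction (CeAOff) central-amygdala groups — each with
sigmoidal firing-rate dynamics

    tau dU/dt = F(net input + eta) - U,    F(x) = 1 / (1 + exp(-Ex (x - Th)))

integrated by noisy Euler stepping (15 ms step, additive Gaussian noise,
mean 0.03, SD 0.1).  Thalamic->LA, hippocampal->BAf and mPFC->BAe weights
learn after each trial by a Rescorla-Wagner prediction-error rule,
`ERR = US - U_CeAOn`, gated Hebbian-style by pre- and postsynaptic rates.
Alcohol enters as published synaptic-weight overlays: acute alcohol raises
local inhibition and weakens BLA->CeA excitation; chronic alcohol raises
CeA inhibition and tonic inhibitory drive and strengthens LA->BAf.

The package is aimed at computational and behavioural neuroscientists who
want to simulate conditioning protocols under these circuit modulations,
reproduce ensemble trials-to-criterion statistics, and analyse extinction
robustness on the reduced CeAOn/CeAOff phase plane.

## Worked example

```r
library(amyfear)

res <- run_session(session_config("naive", seed = 1))
res
#> <session_result> condition: naive
#>   trials: 60 (15 acq / 10 rest / 35 ext)
#>   trials to acquisition: 7
#>   trials to extinction:  8

ens <- run_ensemble(session_config("chronic"), n_sessions = 100,
                    base_seed = 1000)
ens
#> <ensemble_summary> chronic - 100 sessions
#>   acquisition: 7.58 trials (SD 0.50, 100 reached, 0% failed)
#>   extinction:  13.30 trials (SD 0.46, 100 reached, 0% failed)
#>   post-extinction reactivation trials: 25

robustness_rhs(reduced_system_spec(), u_baf = 1, u_la = 1, u_off = 1)
#> [1] 0.8
```

The session result reports how many trials the circuit needed to acquire
the fear response (trial-averaged CeAOn crossing its criterion) and, after
the rest period, to extinguish it (CeAOn falling near zero).  The chronic
ensemble shows the slowed, less reliable extinction produced by the
chronic overlay — including occasional post-extinction reactivation
trials, where noise flips the weakly held CeA switch back to the fear
state.  The robustness value 0.8 is the right-hand side of the extinction
inequality at full activation: naive CeA inhibition (1.5) exceeds it with
a wide margin, so naive extinction is robust.

`plot_session(res)` draws the trial course (BLA activities, CeA
activities, plastic weights; rest shaded, recall trial dashed) and
`plot_phaseplane(reduced_system_spec())` the reduced CeA nullclines,
equilibria and a noisy trajectory.  A command-line interface with
`simulate`, `ensemble`, `sweep`, `compare`, `phaseplane` and `plot`
subcommands is installed at `inst/cli/amyfear`.

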