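# Example amyfear session configuration.  Any key omitted falls back to
# the calibrated defaults; see ?load_config for the full key list.
condition: chronic
seed: 1
n_acq: 15
n_rest: 10
n_ext: 35
W_CeA_inhib: 1.5
Dr_CeA: 0.0
tau: 0.05
alpha: 1.0
Ex: 10
Th: 0.5
noise_mean: 0.03
noise_sd: 0.1
dt: 0.015
steps_trial: 1000
steps_intertrial: 500
I_Hip: 0.4
I_PFC: 0.75
crit_acq: 0.8
crit_ext: 0.1
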