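# Example run configuration for the sasscreen command-line front end.
# Command-line key=value arguments override these keys.
input: example_cohort_synthetic.csv
score: sas          # sas | stop_bang | nosas
score_cutoff: 3.0   # screening positivity cut-off (3.7 balances sens/spec)
ahi_cutoff: 30      # diagnosis cut-off, events/h (presets 5/10/15/20/30/45)
sweep_from: 2.5
sweep_to: 6.0
sweep_by: 0.05
ci_method: delong   # delong | bootstrap
boot: 2000
seed: 1
out_dir: results
figures: false
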