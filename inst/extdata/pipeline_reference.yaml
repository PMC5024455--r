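# End-to-end pipeline configuration: simulate the reference discordance
# scenario, normalize, call fusions at the ten-fold SNR threshold and
# evaluate against the karyotype/FISH truth labels.
simulation:
  scenario: reference
order: background-first
policy: controls_only
threshold: 10
seed: 94
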