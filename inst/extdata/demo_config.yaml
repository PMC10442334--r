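# Demonstration run: a reduced synthetic study so the whole pipeline
# finishes in a few seconds.
seed: 11
simulate:
  n_nfib_sites: 150
  frac_orc1_dependent: 0.5
  knockdown_fc: 2.0
  noise_dispersion: 0.1
stages:
  colocalization: true
  differential: true
  origins: true
  compartments: true
  aux: true
analysis:
  fc_cutoff: 1.2
  ns_fdr: 0.05
  compartment_alpha: 0.05
  em_traces: 200
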