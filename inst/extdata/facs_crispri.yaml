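# Example: CRISPRi FACS screen, 100x representation at every stage
mode: CRISPRi
genome:
  n_genes: 500
  fraction_sigmoidal: 0.25
library:
  guides_per_gene: 5
  fraction_high_activity: 0.9
  frequency_spread: 10
infection:
  moi: 0.25
  representation: 100
selection:
  type: facs
  bin_fraction: 0.25
  noise_sigma: 1.0
  representation: 100
sequencing:
  representation: 100
analysis:
  pseudocount: 0.5
evaluation:
  top_n: 50
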