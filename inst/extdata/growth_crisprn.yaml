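# Example: CRISPRn growth screen, three passages
mode: CRISPRn
genome:
  n_genes: 500
library:
  guides_per_gene: 5
infection:
  moi: 0.25
  representation: 100
selection:
  type: growth
  num_passages: 3
  representation: 100
sequencing:
  representation: 100
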