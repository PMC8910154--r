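# Bundled small synthetic study: two somatic-like groups of three samples
# with planted 4-fold changes in the disease group; desk-scale library
# sizes so the full workflow runs in seconds.
alpha: 0.05
h_grid: [1, 2]
keepX_grid: [5, 10]
sim:
  seed: 42
  n_chroms: 1
  chrom_len: 60000
  n_pirna_loci: 80
  n_decoy_ncrna: 15
  n_repeats: {LINE: 4, SINE: 4, LTR: 3, DNA: 3, simple_repeat: 2}
  n_genes: 12
  n_lncrna: 4
  n_pseudogenes: 3
  groups:
    - {name: control, n_samples: 3, germline: false, de: false}
    - {name: PD, n_samples: 3, germline: false, de: true}
  libsize_lognormal: {meanlog: 7.3, sigma: 0.2}
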