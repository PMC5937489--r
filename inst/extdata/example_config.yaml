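# Example analysis configuration.
#
# The canonical attB/attP sequences below are the package's synthetic
# stand-in set (see ?canonical_att_synthetic). For analyses of real data,
# replace them with the published sequences of your integrase system,
# either inline or as paths to single-record FASTA files.
canonical:
  attB: ACTGCAAGTTCACGGATCGGCTACTCATCGGGACTGTAGTCCCGATGAGTAGCCGATCCGTGAACTTGCAGTC
  attB_core: 36
  attP: GGTACCATTCACTCGATCGGACTGTAGTCGATCGAGTGAATGGTACCGG
  attP_core: 24
  minimal_arm_left: 17
  minimal_arm_right: 17
  crossover_arm_left: 3
  crossover_arm_right: 4
  provenance: synthetic example set

sim:
  seed: 1
  genome_length: 200000
  gc_fraction: 0.68
  n_sites: 20
  n_transformants: 27
  n_reactions: 14
  plasmid_length: 6000
  topology: circular

detect:
  anchor_k: 21

scan:
  threshold: 1.0e-8
  pseudocount: 0.5
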