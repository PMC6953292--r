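# Example run configuration for the mspls command-line wrapper.
# Three blocks measured on the same samples; X1 and X2 are mutually
# response (symmetric relation) and X3 is response for both, so X3 is the
# terminal block whose variance the selected variables explain.
blocks:
  - X1.csv
  - X2.csv
  - X3.csv
block_names: [X1, X2, X3]
connectivity:        # C[q, q'] = 1: block q is response for block q'
  - [0, 1, 0]
  - [1, 0, 0]
  - [1, 1, 0]
penalty:
  kind: ust          # ust | enet | cardinality
  lambda1: 50
cv:
  folds: 10
inference:
  B_perm: 1000
  B_boot: 1000
components:
  count: 2
seed: 42
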