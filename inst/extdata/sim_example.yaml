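# Example simulation: two clades of three leaves plus a two-leaf
# outgroup, 150 sites, with a counterion-style site (113) charged in
# cladeA and uncharged in cladeB.
tree: "(((A1:0.1,A2:0.1,A3:0.1):0.3,(B1:0.1,B2:0.1,B3:0.1):0.3):0.3,(og1:0.1,og2:0.1):0.3);"
root_seq_length: 150
seed: 101
clades:
  cladeA: [A1, A2, A3]
  cladeB: [B1, B2, B3]
  outgroup: [og1, og2]
constrained_sites:
  "113":
    root: E
    cladeA: E
    cladeB: F
    outgroup: F
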