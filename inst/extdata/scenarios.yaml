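# Scenario file for `coarsen-causal simulate`. Each entry names a built-in
# generating truth (see ?cc_scenario), the strata builder, the units per
# replicate and the strata count (integer; omit for ceiling(sqrt(n))).
scenarios:
  - scenario: linear
    method: kmeans
    n: 500
    strata: 20
  - scenario: "null"
    method: kmeans
    n: 500
    strata: 20
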