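# Aggregation-only run from published fractions and per-species totals
# (a triprotic phenol + HOO. at physiological pH).
mode: as-printed
pH: 7.4
temperature: 298.15
fractions:
  H3W: 0.942
  H2W-: 0.058
k_totals:
  H3W: 1.99e+4
  H2W-: 1.35e+8
k_total_lipid: 4.84e+5
references:
  - label: Trolox
    k: 9.70e+4
    scope: lipid
  - label: ascorbic acid
    k: 7.80e+4
    scope: lipid
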