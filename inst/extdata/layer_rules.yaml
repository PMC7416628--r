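# Ordered anatomical-layer rules: overrides win, then the first matching
# rule, then the default.  Fields may be sysgo_set2, sysgo_set3 or
# loc_set3.
rules:
- field: sysgo_set3
  values: [Immune system and Inflammation]
  layer: AL1
- field: sysgo_set3
  values: [ECM organization]
  layer: AL2
- field: sysgo_set3
  values: [Cell junction and adhesion]
  layer: AL3
- field: loc_set3
  values: [Extracellular, Plasma membrane]
  layer: AL4
- field: sysgo_set3
  values: [Metabolism]
  layer: AL5
- field: loc_set3
  values: [Cytosol, Nucleus, Mitochondria, Endomembrane system,
           Vesicles and lysosomes, Cytoskeleton]
  layer: AL6
default: unassigned
overrides: {}
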