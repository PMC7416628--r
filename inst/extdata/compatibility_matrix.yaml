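# Compartment compatibility over the 8-level localization scheme.
# Pairs listed under 'disallowed' cannot physically interact (separated
# compartments with no shared membrane or lumen); every other pair, and
# every same-compartment pair, is allowed.  Edit freely.
compartments:
- Extracellular
- Plasma membrane
- Cytosol
- Nucleus
- Mitochondria
- Endomembrane system
- Vesicles and lysosomes
- Cytoskeleton
disallowed:
- - Extracellular
  - Cytosol
- - Extracellular
  - Nucleus
- - Extracellular
  - Mitochondria
- - Extracellular
  - Cytoskeleton
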