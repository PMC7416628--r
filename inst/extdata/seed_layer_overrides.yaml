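# Published layer placements for the 22 anchor risk proteins of the
# human choroid/RPE/NR analysis.  Layer placement in the source analysis
# drew on manual curation beyond the rule engine, so these ship as
# explicit overrides; genes placed in two layers there (EGFR, PDGFRA,
# KCNJ2 appear in both AL4 and AL6) carry their surface-facing layer
# here, since an override maps each node to a single stratum.
rules: []
default: unassigned
overrides:
  CD53: AL1
  CMTM7: AL1
  GZMB: AL1
  TSPAN11: AL1
  C6orf223: AL1
  TDRP: AL1
  PLXNC1: AL1
  COL8A1: AL2
  TNR: AL2
  ADGRL3: AL3
  CDH6: AL3
  EMP2: AL3
  ERC2: AL3
  POSTN: AL3
  EGFR: AL4
  PDGFRA: AL4
  KCNJ2: AL4
  SLC1A7: AL4
  CBS: AL5
  SLC16A8: AL5
  DPF3: AL6
  PRRX2: AL6
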