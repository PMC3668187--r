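# Published patient counts from the consecutive breast-cancer TMA
# cohort used to validate the ANLN/PBK/PDZK1 panel: per-marker
# evaluable and high-expression counts, total cohort size, and the
# number of patients with a score for all three markers.
cohort_size: 512
complete_cases: 252
markers:
  ANLN:
    evaluable: 479
    high: 309
  PBK:
    evaluable: 292
    high: 105
  PDZK1:
    evaluable: 280
    high: 43
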