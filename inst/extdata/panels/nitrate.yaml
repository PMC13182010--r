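# Dissimilatory nitrate reduction to ammonia: periplasmic nitrate
# reductase (napA, napB) plus NADH-dependent nitrite reductase
# (nirB, nirD). All four genes required for the verdict.
panel_id: nitrate_reduction
verdict_rule: all_required
markers:
  - {name: napA, match_by: ko, accepted_ids: [K02567]}
  - {name: napB, match_by: ko, accepted_ids: [K02568]}
  - {name: nirB, match_by: ko, accepted_ids: [K00362]}
  - {name: nirD, match_by: ko, accepted_ids: [K00363]}
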