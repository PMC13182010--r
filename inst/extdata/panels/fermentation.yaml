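# Fermentation end products (lactate, acetate, fumarate, citrate, malate,
# succinate). Report-only: the KO set per product is a documented curation
# of canonical terminal enzymes, not an exhaustive pathway model.
panel_id: fermentation
verdict_rule: report_only
markers:
  - {name: lactate_ldh,   match_by: ko, accepted_ids: [K00016]}
  - {name: acetate_ackA,  match_by: ko, accepted_ids: [K00925], subsystem: acetate_pta_ack}
  - {name: acetate_pta,   match_by: ko, accepted_ids: [K00625], subsystem: acetate_pta_ack}
  - {name: fumarate_fumC, match_by: ko, accepted_ids: [K01679]}
  - {name: citrate_gltA,  match_by: ko, accepted_ids: [K01647]}
  - {name: malate_mdh,    match_by: ko, accepted_ids: [K00024]}
  - {name: succinate_frdA, match_by: ko, accepted_ids: [K00244]}
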