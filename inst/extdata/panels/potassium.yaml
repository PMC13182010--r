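# Primary osmotic-stress response: potassium ion uptake. The inducible
# high-affinity Kdp system is a joint subsystem; the constitutive Trk
# system components are reported individually. Report-only: potassium
# uptake is near-universal and not itself an osmoadaptation verdict.
panel_id: potassium_uptake
verdict_rule: report_only
markers:
  - {name: kdpA, match_by: ko, accepted_ids: [K01546], subsystem: kdp_system}
  - {name: kdpB, match_by: ko, accepted_ids: [K01547], subsystem: kdp_system}
  - {name: kdpC, match_by: ko, accepted_ids: [K01548], subsystem: kdp_system}
  - {name: kdpD, match_by: ko, accepted_ids: [K07646], subsystem: kdp_system}
  - {name: kdpE, match_by: ko, accepted_ids: [K07667], subsystem: kdp_system}
  - {name: trkH, match_by: ko, accepted_ids: [K03498]}
  - {name: trkA, match_by: ko, accepted_ids: [K03499]}
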