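# Chemotaxis signal transduction and flagellar switch/motor genes.
# Verdict true iff the full signalling set is present. MCP and Aer
# receptor counting is handled separately by count_mcps().
panel_id: chemotaxis
verdict_rule: all_required
markers:
  - {name: cheA, match_by: ko, accepted_ids: [K03407]}
  - {name: cheW, match_by: ko, accepted_ids: [K03408]}
  - {name: cheV, match_by: ko, accepted_ids: [K03415]}
  - {name: cheB, match_by: ko, accepted_ids: [K03412]}
  - {name: cheR, match_by: ko, accepted_ids: [K00575]}
  - {name: cheD, match_by: ko, accepted_ids: [K03411]}
  - {name: cheY, match_by: ko, accepted_ids: [K03413]}
  - {name: cheZ, match_by: ko, accepted_ids: [K03414]}
  - {name: cheX, match_by: ko, accepted_ids: [K03409]}
  - {name: fliG, match_by: ko, accepted_ids: [K02410]}
  - {name: fliM, match_by: ko, accepted_ids: [K02416]}
  - {name: fliN, match_by: ko, accepted_ids: [K02417]}
  - {name: motA, match_by: ko, accepted_ids: [K02556]}
  - {name: motB, match_by: ko, accepted_ids: [K02557]}
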