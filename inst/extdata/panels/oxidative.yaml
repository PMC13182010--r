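# Oxidative-stress defence enzymes and high-affinity terminal oxidases,
# matched by COG id. Multi-COG cytochrome complexes require all listed
# COG ids jointly (copy number = minimum per-id count). Markers tagged
# high_affinity_oxidase drive the microaerobe flag in oxidative_profile().
panel_id: oxidative
verdict_rule: report_only
markers:
  - {name: catalase,               match_by: cog_id, accepted_ids: [COG0376]}
  - {name: glutathione_peroxidase, match_by: cog_id, accepted_ids: [COG0386]}
  - {name: peroxidase_COG1858,     match_by: cog_id, accepted_ids: [COG1858]}
  - {name: peroxidase_COG2128,     match_by: cog_id, accepted_ids: [COG2128]}
  - {name: peroxidase_COG2837,     match_by: cog_id, accepted_ids: [COG2837]}
  - name: cytochrome_cbb3
    match_by: cog_id
    accepted_ids: [COG2010, COG4736, COG2993, COG3278]
    match_all: true
    class: high_affinity_oxidase
  - name: cytochrome_bd
    match_by: cog_id
    accepted_ids: [COG1294, COG1271]
    match_all: true
    class: high_affinity_oxidase
  - name: cytochrome_b562
    match_by: cog_id
    accepted_ids: [COG3783]
    class: high_affinity_oxidase
  - name: cytochrome_c_oxidase
    match_by: cog_id
    accepted_ids: [COG1845, COG0843, COG1622]
    match_all: true
    class: high_affinity_oxidase
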