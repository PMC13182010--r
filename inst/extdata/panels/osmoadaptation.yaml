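# Compatible-solute osmoadaptation panel: uptake of osmoprotectants
# (choline, glycine betaine, carnitine, proline/ectoine permease) and
# biosynthesis (glycine betaine from choline, proline, ectoine, carnitine
# degradation, trehalose). Verdict: at least one transport OR biosynthesis
# subsystem complete. The proU transporter requires proV + proW + proX
# jointly. Carnitine dehydrogenase genes carry no stable KO and are
# matched against product text by gene symbol.
panel_id: osmoadaptation
verdict_rule: any_complete_subsystem
markers:
  # --- osmoprotectant transport ---
  - {name: betT, match_by: ko, accepted_ids: [K02168]}
  - {name: proV, match_by: ko, accepted_ids: [K02000], subsystem: proU_transport}
  - {name: proW, match_by: ko, accepted_ids: [K02001], subsystem: proU_transport}
  - {name: proX, match_by: ko, accepted_ids: [K02002], subsystem: proU_transport}
  - {name: caiT, match_by: ko, accepted_ids: [K05245]}
  - {name: proP, match_by: ko, accepted_ids: [K03762]}
  # --- glycine betaine biosynthesis from choline ---
  - {name: betA, match_by: ko, accepted_ids: [K00108], subsystem: betaine_synthesis}
  - {name: betB, match_by: ko, accepted_ids: [K00130], subsystem: betaine_synthesis}
  # --- proline biosynthesis ---
  - {name: proA, match_by: ko, accepted_ids: [K00147], subsystem: proline_synthesis}
  - {name: proB, match_by: ko, accepted_ids: [K00931], subsystem: proline_synthesis}
  - {name: proC, match_by: ko, accepted_ids: [K00286], subsystem: proline_synthesis}
  # --- ectoine biosynthesis ---
  - {name: ectA, match_by: ko, accepted_ids: [K06718], subsystem: ectoine_synthesis}
  - {name: ectB, match_by: ko, accepted_ids: [K00836], subsystem: ectoine_synthesis}
  - {name: ectC, match_by: ko, accepted_ids: [K06720], subsystem: ectoine_synthesis}
  # --- carnitine degradation/synthesis ---
  - {name: cdhA, match_by: gene_symbol, accepted_ids: [cdhA], subsystem: carnitine_pathway}
  - {name: cdhB, match_by: gene_symbol, accepted_ids: [cdhB], subsystem: carnitine_pathway}
  - {name: cdhC, match_by: gene_symbol, accepted_ids: [cdhC], subsystem: carnitine_pathway}
  # --- trehalose biosynthesis routes ---
  - {name: tps,  match_by: ko, accepted_ids: [K00697], subsystem: trehalose_otsAB}
  - {name: tpp,  match_by: ko, accepted_ids: [K01087], subsystem: trehalose_otsAB}
  - {name: treS, match_by: ko, accepted_ids: [K05343]}
  - {name: treY, match_by: ko, accepted_ids: [K06044], subsystem: trehalose_treYZ}
  - {name: treZ, match_by: ko, accepted_ids: [K01236], subsystem: trehalose_treYZ}
  - {name: treP, match_by: ko, accepted_ids: [K00691]}
  - {name: treT, match_by: ko, accepted_ids: [K13057]}
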