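# Sugar transporter system definitions.
#
# ABC importers require a substrate-binding protein (SBP), transmembrane
# domain(s) (TMD) and a nucleotide-binding domain (NBD/ATPase); PTS systems
# require enzyme I (EI), the phosphocarrier HPr, and a substrate-specific
# enzyme II complex (EII). EI and HPr are genome-global (one copy serves
# all EII complexes) and are declared once under pts_common.
#
# Role -> KO maps are curated from KEGG module/orthology definitions for
# the sugars of interest; the file is data and can be overridden.
pts_common:
  EI:  [K08483]          # ptsI, phosphoenolpyruvate-protein phosphotransferase
  HPr: [K02784]          # ptsH, phosphocarrier protein
systems:
  - system_id: abc_maltose
    kind: ABC
    substrate: maltose/maltodextrin
    roles:
      SBP: [K10108]                # malE
      TMD: [K10109, K10110]        # malF, malG
      NBD: [K10111]                # malK
  - system_id: abc_glucose_mannose
    kind: ABC
    substrate: glucose/mannose
    roles:
      SBP: [K17315]                # gtsA
      TMD: [K17316, K17317]        # gtsB, gtsC
      NBD: [K17318]                # gtsD
  - system_id: abc_ribose
    kind: ABC
    substrate: ribose
    roles:
      SBP: [K10439]                # rbsB
      TMD: [K10440]                # rbsC
      NBD: [K10441]                # rbsA
  - system_id: pts_glucose
    kind: PTS
    substrate: glucose
    roles:
      EII: [K02777, K02778, K02779]   # crr / ptsG components
  - system_id: pts_glcnac
    kind: PTS
    substrate: GlcNAc
    roles:
      EII: [K02802, K02803, K02804]   # nagE components
  - system_id: pts_fructose
    kind: PTS
    substrate: fructose
    roles:
      EII: [K02768, K02769, K02770]   # fruA/fruB components
  - system_id: pts_maltose_glucose
    kind: PTS
    substrate: maltose/glucose
    roles:
      EII: [K02790, K02791]           # malX components
  - system_id: pts_trehalose
    kind: PTS
    substrate: trehalose
    roles:
      EII: [K02817, K02818, K02819]   # treB components
  - system_id: pts_mannitol
    kind: PTS
    substrate: mannitol
    roles:
      EII: [K02798, K02799, K02800]   # mtlA components
  - system_id: pts_galnac
    kind: PTS
    substrate: GalNAc
    roles:
      EII: [K02744, K02745, K02746]   # aga components
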