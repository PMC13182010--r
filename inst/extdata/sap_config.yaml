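# Sugar-Acid Preference (SAP) index configuration.
# SAP = tanh(s*S + a*A) where S and A are the fractions of annotated ORFs
# assigned to sugar- and acid-metabolism KOs.
#
# The coefficients are the published calibration (s = 60.76, a = -20.21).
# The KO sets below are a compact curation of sugar-catabolism and
# organic-acid-utilization markers; the original curated gene list is not
# redistributed here, so replace these sets with it for production use.
s: 60.76
a: -20.21
sugar_kos:
  - K00844   # hexokinase
  - K00845   # glucokinase
  - K01810   # glucose-6-phosphate isomerase
  - K00850   # 6-phosphofructokinase
  - K01623   # fructose-bisphosphate aldolase, class I
  - K01624   # fructose-bisphosphate aldolase, class II
  - K01785   # galactose mutarotase
  - K00849   # galactokinase
  - K01805   # xylose isomerase
  - K00854   # xylulokinase
  - K01222   # 6-phospho-beta-glucosidase
  - K02777   # PTS glucose EIIA
acid_kos:
  - K00016   # L-lactate dehydrogenase
  - K00101   # L-lactate oxidase/dehydrogenase (cytochrome)
  - K00024   # malate dehydrogenase (decarboxylating)
  - K01679   # fumarate hydratase class II
  - K00925   # acetate kinase
  - K00625   # phosphate acetyltransferase
  - K01026   # propionate CoA-transferase
  - K00244   # fumarate reductase flavoprotein subunit
  - K01596   # PEP carboxykinase
  - K00169   # pyruvate:ferredoxin oxidoreductase alpha
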