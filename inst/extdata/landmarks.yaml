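# Copiotroph/oligotroph reference landmark set: 33 COG (sub)categories,
# 14 with direction "+" (higher normalized gene counts indicate
# copiotrophy) and 19 with direction "-" (the opposite).
#
# The numeric reference values for the "average copiotroph" and "average
# oligotroph" are NOT shipped: they come from the published reference
# scheme's supplementary material and must be filled in by the user
# (replace the nulls). The category ids and the direction split are
# curated here; directions beyond the handful the primary analysis states
# explicitly are part of that curation. Values are normalized gene counts
# per Mb (unit: per_mb) unless you switch a category to per_orf.
#
# synthetic_landmarks() fills this skeleton with synthetic stand-in values
# for simulation and testing.
unit: per_mb
landmarks:
  # ---- copiotrophy-associated (+): 14 ----
  - {category: "Q",       direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: "I",       direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: "N",       direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: "T",       direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1804, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0183, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1028, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0318, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1024, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1960, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1263, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0625, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_3325, direction: "+", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0840, direction: "+", oligotroph_value: null, copiotroph_value: null}
  # ---- oligotrophy-associated (-): 19 ----
  - {category: "V",       direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: "K",       direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0737, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_2124, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1680, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0583, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_3710, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1653, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0834, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0683, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0747, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0601, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1173, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_1175, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0745, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_2197, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_2771, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_0784, direction: "-", oligotroph_value: null, copiotroph_value: null}
  - {category: COG_3839, direction: "-", oligotroph_value: null, copiotroph_value: null}
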