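# Machinery models: secretion systems, flagellum and type IV pili.
# Mandatory role lists mirror the MacSyFinder/TXSScan (and ConjScan for
# T4SS) model definitions at the granularity this pipeline adjudicates;
# the T2SS (13 mandatory genes) and T4SS_G (17) totals anchor the
# missing-fraction arithmetic. A machinery missing more than
# highly_incomplete_fraction (default 1/3) of its mandatory roles and not
# rescued is classed highly incomplete.
models:
  - model_id: T1SS
    mandatory_genes: [abc, mfp, omf]
  - model_id: T2SS
    mandatory_genes: [gspC, gspD, gspE, gspF, gspG, gspH, gspI, gspJ,
                      gspK, gspL, gspM, gspN, gspO]
  - model_id: T3SS
    mandatory_genes: [sctC, sctJ, sctN, sctQ, sctR, sctS, sctT, sctU, sctV]
  - model_id: T4SS_F
    mandatory_genes: [traL, traE, traK, traB, traV, traC, traW, traU,
                      traN, traF, traH, traG]
  - model_id: T4SS_G
    mandatory_genes: [tfc3, tfc4, tfc5, tfc6, tfc7, tfc8, tfc9, tfc10,
                      tfc11, tfc12, tfc13, tfc14, tfc15, tfc16, tfc17,
                      tfc18, tfc19]
  - model_id: T5SS
    mandatory_genes: [t5ss_translocator]
  - model_id: T6SS
    mandatory_genes: [tssA, tssB, tssC, tssD, tssE, tssF, tssG, tssH,
                      tssI, tssJ, tssK, tssL, tssM]
  - model_id: Flagellum
    mandatory_genes: [flgB, flgC, flgH, flgI, flhA, flhB, fliE, fliF,
                      fliG, fliM, fliN, motA, motB]
  - model_id: Tad
    mandatory_genes: [tadA, tadB, tadC, tadV, rcpA, rcpC, flp]
  - model_id: MSH
    mandatory_genes: [mshA, mshE, mshG, mshL, mshM, mshN]
  - model_id: T4aP
    mandatory_genes: [pilA, pilB, pilC, pilD, pilM, pilN, pilO, pilP,
                      pilQ, pilT]
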