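# Long-read scaffolding tuning: four scaffolder parameters, single
# response (scaffold N50, maximized; no limits needed in single-response
# mode).  Reduction factor defaults to the number of factors (4).
design:
  factors:
    ALEN: {type: ordinal, min: 0, max: 5000}
    GLEN: {type: ordinal, min: -3000, max: 3000}
    RRAT: {type: quantitative, min: 0.1, max: 0.7}
    IDEN: {type: ordinal, min: 30, max: 90}
  responses:
    N50: {criterion: maximize}
  optimization_design: ccf
  shrinkage: 0.9
  model_selection: greedy
pipeline:
  steps:
    - name: scaffold_and_measure
      command: >-
        Rscript "$DOEOPT_MOCK" --spec "$DOEOPT_SPEC" --out results.txt
        ALEN={{ALEN}} GLEN={{GLEN}} RRAT={{RRAT}} IDEN={{IDEN}}
execution:
  mode: sequential
  workdir: doeopt_work
  results_file: results.txt
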