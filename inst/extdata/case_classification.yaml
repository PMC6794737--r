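# Long-read taxonomic classification tuning: three classifier parameters,
# single response (F1 score of target vs near-neighbor discrimination).
design:
  factors:
    MH: {type: ordinal, min: 1, max: 200}
    PRES: {type: ordinal, min: 10, max: 18}
    FILT: {type: quantitative, min: 0, max: 0.05}
  responses:
    F1: {criterion: maximize}
  optimization_design: ccf
  shrinkage: 0.9
  model_selection: greedy
pipeline:
  steps:
    - name: classify_and_score
      command: >-
        Rscript "$DOEOPT_MOCK" --spec "$DOEOPT_SPEC" --out results.txt
        MH={{MH}} PRES={{PRES}} FILT={{FILT}}
execution:
  mode: sequential
  workdir: doeopt_work
  results_file: results.txt
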