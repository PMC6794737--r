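# Variant-calling step tuning (first of two sequential optimizations):
# four caller parameters, single response (indel F1), GSD reduction 8.
design:
  factors:
    GMQ: {type: ordinal, min: 20, max: 55}
    MBQ: {type: ordinal, min: 5, max: 25}
    RAS: {type: ordinal, min: 5, max: 25}
    SCC: {type: quantitative, min: 5, max: 25}
  responses:
    F1: {criterion: maximize}
  reduction_factor: 8
  optimization_design: ccf
  shrinkage: 0.9
  model_selection: greedy
pipeline:
  steps:
    - name: call_and_benchmark
      command: >-
        Rscript "$DOEOPT_MOCK" --spec "$DOEOPT_SPEC" --out results.txt
        GMQ={{GMQ}} MBQ={{MBQ}} RAS={{RAS}} SCC={{SCC}}
execution:
  mode: sequential
  workdir: doeopt_work
  results_file: results.txt
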