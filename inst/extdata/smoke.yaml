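# Minimal smoke-test scenario: 2 x 2 grid exercising the full pipeline.
sweep:
  glucose: [1, 6]
  faa: [0, 1]
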