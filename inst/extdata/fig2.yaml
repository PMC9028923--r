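# Membrane-potential trace comparison scenario: low/high glucose at
# low/high amino-acid levels (use with compareTraces()).
sweep:
  glucose: [1, 6]
  faa: [0, 1]
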