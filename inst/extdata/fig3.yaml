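# cAMP decomposition scenario: glucose grid at three amino-acid levels;
# feeds the stacked sAC/tmAC decomposition and the ATP curve.
sweep:
  glucose: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  faa: [0, 0.5, 1]
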