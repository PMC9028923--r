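# Dose-response scenario: glucose 0-10 mM at low/medium/high amino-acid
# levels; feeds the RGS curves and the amino-acid fold-change report.
sweep:
  glucose: [0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5,
            5.5, 6, 6.5, 7, 7.5, 8, 8.5, 9, 9.5, 10]
  faa: [0, 0.5, 1]
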