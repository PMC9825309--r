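Name: synthetic_contaminant_peg_437
PrecursorMZ: 437.2543
Num Peaks: 4
89.0597 100
133.0859 60
177.1121 35
221.1384 18

Name: synthetic_plasticizer_391
PrecursorMZ: 391.2843
Num Peaks: 3
149.0233 100
167.0339 40
279.1591 22

Name: synthetic_background_519
MW: 1036.5021
Charge: 2
Num Peaks: 2
255.2330 100
283.2643 55
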