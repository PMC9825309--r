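ms_level,mz_lower,mz_upper,duration_s
1,,,0.05
2,400,440,0.02
2,420,460,0.02
2,440,480,0.02
2,460,500,0.02
2,480,520,0.02
2,500,540,0.02
2,520,560,0.02
2,540,580,0.02
2,560,600,0.02
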