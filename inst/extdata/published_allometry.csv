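group,n,slope,intercept
Epitheria,35,0.74,-5.31
Prototheria+Metatheria,26,0.74,-5.47
Xenarthra,14,0.74,-5.77
Xenarthra_fossil,14,0.74,-5.35
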