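group_a,group_b,z,p_bonferroni
Epitheria,Prototheria+Metatheria,-2.04,0.2478
Epitheria,Xenarthra,-4.99,0.001
Epitheria,Xenarthra_fossil,-0.39,1
Prototheria+Metatheria,Xenarthra,-3.15,0.01
Prototheria+Metatheria,Xenarthra_fossil,1.08,1
Xenarthra,Xenarthra_fossil,3.45,0.003
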