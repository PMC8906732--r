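species,a_w_nm,a_i,f_w_nm,f_i
PC,433,0.192,577,0.128
PC1,430,0.214,565,0.141
PC2,486.8,0.096,718,0.063
PC3,475,0.110,702,0.070
V,440,0.958,493,0.990
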