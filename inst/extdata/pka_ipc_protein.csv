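group,type,pka
Nterm,basic,9.094
Cterm,acidic,2.869
D,acidic,3.872
E,acidic,4.412
C,acidic,7.555
Y,acidic,10.85
H,basic,5.637
K,basic,9.052
R,basic,11.84
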