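group,type,pka
Nterm,basic,8.6
Cterm,acidic,3.6
D,acidic,3.9
E,acidic,4.1
C,acidic,8.5
Y,acidic,10.1
H,basic,6.5
K,basic,10.8
R,basic,12.5
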