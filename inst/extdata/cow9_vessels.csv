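"name","x_mm","y_mm"
"ACA",0,32
"RMCA1",38,14
"RMCA2",42,4
"RMCA3",40,-6
"LMCA1",-38,14
"LMCA2",-42,4
"LMCA3",-40,-6
"RPCA",10,-30
"LPCA",-10,-30
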