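time_min,conc_pM
2880,4.27663322978778
10080,11.376181746352
20160,15.5894615638436
30240,13.2781353085857
40320,16.9634006898963
50400,24.6105212701731
60480,28.8091958207053
70560,27.4188683662292
80640,14.9615797581245
90720,12.749930113445
100800,7.20605248206141
110880,3.63020583102281
120960,1.61672698256634
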