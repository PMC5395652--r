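time_min,conc_pM
2880,1.02863917544041
10080,3.45119316710209
20160,4.03340273049781
30240,3.56430569495253
40320,4.90529442633747
50400,7.76286413972362
60480,7.56443402548474
70560,6.15836290537809
80640,4.98721808757463
90720,3.08795362649997
100800,1.4985977438801
110880,0.969769945021551
120960,0.508179482396104
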