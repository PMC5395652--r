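time_min,conc_pM
2880,1.96382073884265
10080,6.83775393697607
20160,7.42005149955131
30240,7.70342192238076
40320,9.27403474348993
50400,14.4538306550076
60480,10.1620062092843
70560,12.491848015326
80640,8.45293623068809
90720,7.1768570229111
100800,3.50295133917764
110880,1.72262507106248
120960,0.94244802751687
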