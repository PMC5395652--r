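{"timescale":"long","dose_mg":2.5,"bodyweight_kg":90,"truth":{"n1":10,"a1":675,"ktr1":0.00015,"n2":4,"a2":200,"ktr2":0.00018,"r1":0.03,"k1":0.00764,"r2":0.005,"k2":0.000476},"meta":{"schedule":"sparse","seed":1025,"noise":{"family":"student_t","sigma":0.1,"df":4},"n_redraws":0}}
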