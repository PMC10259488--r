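mouse_id,day,weight_g
ex1,1,26.0
ex1,3,25.8
ex1,5,25.7
ex2,1,24.2
ex2,3,24.0
ex2,5,23.7
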