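family_id,cycle,protocol,total_retrieved,gv,mi,pb1,fertilized,cleaved
F1,1,IVF modified ultra-long,11,0,11,0,0,0
F1,2,IVF mild stimulation,6,1,5,0,0,0
F1,3,IVF PPOS,13,0,13,0,0,0
F2,1,IVF PPOS,9,0,9,0,0,0
F3,1,IVF natural,1,0,1,0,0,0
F3,2,IVF short,4,0,4,0,0,0
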