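type,node_a,node_b,context
assoc,obesity,htn,
assoc,obesity,predm,
assoc,htn,cevd,
assoc,predm,dm,
causal_pos,obesity,htn,
causal_pos,blood pressure,cevd,
causal_neg,dm,cevd,htn
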