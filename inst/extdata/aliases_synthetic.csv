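evidence_name,event_code
obesity,ob
blood pressure,sbp
blood pressure,dbp
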