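carrier_id,organ,age_at_diagnosis
A,endometrium,48
B,colorectum,45
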