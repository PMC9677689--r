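carrier_id,age_at_inclusion,age_at_last_observation,dead,age_at_death
A,42,50,0,
B,40,45,1,45
C,42,44,0,
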