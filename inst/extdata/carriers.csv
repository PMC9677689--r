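carrier_id,gene,gender,region,carrier_status
A,MLH1,female,NO,pathogenic
B,MSH2,male,NO,pathogenic
C,MLH1,male,UK,pathogenic
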