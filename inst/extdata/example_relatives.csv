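proband_id,relation,age_years,endorsement_symptoms,endorsement_treatment
P001,parent,72,1,1
P001,parent,72,0,0
P001,sibling,48,1,0
P002,parent,58,0,0
P002,parent,61,0,0
P002,sibling,35,0,0
P002,sibling,31,1,1
P003,parent,80,0,0
P003,parent,77,1,1
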