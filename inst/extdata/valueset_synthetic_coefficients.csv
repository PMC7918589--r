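term,value
mo2,0.05
mo3,0.07
mo4,0.16
mo5,0.33
sc2,0.05
sc3,0.07
sc4,0.13
sc5,0.26
ua2,0.05
ua3,0.06
ua4,0.11
ua5,0.21
pd2,0.06
pd3,0.08
pd4,0.19
pd5,0.39
ad2,0.07
ad3,0.09
ad4,0.20
ad5,0.41
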