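roi,label
61,lh_IFG
63,lh_aINS_IFG
140,lh_SMG
151,lh_PT
221,rh_lOFC
351,rh_aSTS
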