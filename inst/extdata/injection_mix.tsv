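component	concentration_ng_ul
pCFJ2474_Cas9	25
pSEM235_co-injection_marker	10
pSEM238_HisCl1_selection	10
pSEM318_sgRNA	15
repair_template	10
DNA_ladder_carrier	30
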