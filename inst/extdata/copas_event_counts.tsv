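# Gated adult event counts per strain from the published COPAS quantification; NegCtrl = non-transgenic N2.
strain	n_events
NegCtrl	64
mex-5p	179
klp-19p	134
his-68p	156
W05F2.3p	195
spn-4p	160
pos-1p	75
mei-2p	238
Y75B12B.1p	103
puf-5p	104
mesp-1p	91
puf-11p	109
F23A7.8p	54
clec-87p	75
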