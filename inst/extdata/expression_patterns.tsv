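# Visual GFP expression-pattern classification of the 18 candidate promoters (single-copy reporter insertions).
promoter_id	pattern
his-61p	somatic_and_germline
his-64p	somatic_and_germline
hil-4p	somatic_and_germline
rla-0p	somatic_and_germline
rpl-7Ap	somatic_and_germline
Y37E3.8p	somatic_and_germline
puf-11p	none
F23A7.8p	none
clec-87p	none
klp-19p	germline_specific
his-68p	germline_specific
W05F2.3p	germline_specific
spn-4p	germline_specific
pos-1p	germline_specific
Y75B12B.1p	germline_specific
puf-5p	germline_specific
mei-2p	germline_specific
mesp-1p	germline_specific
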