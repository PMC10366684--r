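# Characterized promoter panel: 2 controls + 18 candidates, transcribed from the published characterization study.
# Each FASTA record is the synthesized promoter as printed: endogenous promoter, 15 bp cloning linker (aaaagcaggctaaaa), then the reporter ATG.
# md5 of concatenated uppercase sequences: a03f783237fe92dd96581c3c337b677c
promoter_id	gene	role	linker	has_atg	total_length_bp	endogenous_length_bp
eef-1A.1p	eef-1A.1	control	aaaagcaggctaaaa	TRUE	597	579
mex-5p	mex-5	control	aaaagcaggctaaaa	TRUE	554	536
his-61p	his-61	candidate	aaaagcaggctaaaa	TRUE	345	327
his-64p	his-64	candidate	aaaagcaggctaaaa	TRUE	272	254
hil-4p	hil-4	candidate	aaaagcaggctaaaa	TRUE	630	612
rla-0p	rla-0	candidate	aaaagcaggctaaaa	TRUE	753	735
rpl-7Ap	rpl-7A	candidate	aaaagcaggctaaaa	TRUE	307	289
Y37E3.8p	Y37E3.8	candidate	aaaagcaggctaaaa	TRUE	766	748
klp-19p	klp-19	candidate	aaaagcaggctaaaa	TRUE	326	308
his-68p	his-68	candidate	aaaagcaggctaaaa	TRUE	386	368
W05F2.3p	W05F2.3	candidate	aaaagcaggctaaaa	TRUE	319	301
spn-4p	spn-4	candidate	aaaagcaggctaaaa	TRUE	606	588
pos-1p	pos-1	candidate	aaaagcaggctaaaa	TRUE	636	618
Y75B12B.1p	Y75B12B.1	candidate	aaaagcaggctaaaa	TRUE	685	667
puf-5p	puf-5	candidate	aaaagcaggctaaaa	TRUE	598	580
mei-2p	mei-2	candidate	aaaagcaggctaaaa	TRUE	324	306
mesp-1p	mesp-1	candidate	aaaagcaggctaaaa	TRUE	537	519
puf-11p	puf-11	candidate	aaaagcaggctaaaa	TRUE	898	880
F23A7.8p	F23A7.8	candidate	aaaagcaggctaaaa	TRUE	578	560
clec-87p	clec-87	candidate	aaaagcaggctaaaa	TRUE	433	415
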