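replicon	size_bp	gc_pct	cds	assigned	conserved_hypothetical	hypothetical	tRNA	rRNA	IS_elements	transposons
CHR1	3928089	63.82	3766	2784	690	250	54	2	30	8
CHR2	2580084	63.60	2493	1468	478	292	8	2	19	7
pMOL28	171459	60.50	175	100	54	15	0	0	3	2
pMOL30	233720	60.13	283	166	52	54	0	0	5	2
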