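# HMO structure library: compositions are literature values for the named
# structures; rt_ref_min values are SYNTHETIC placeholders on a plausible
# porous-graphitized-carbon elution axis (no public RT library ships machine-
# readable values). All entries are alditols (borohydride-reduced pools).
name	hex	hexnac	fuc	neu5ac	reduced	rt_ref_min	isomer_group
2'FL	2	0	1	0	TRUE	6.0	FL
3FL	2	0	1	0	TRUE	8.2	FL
LDFT	2	0	2	0	TRUE	9.5	LDFT
3'SL	2	0	0	1	TRUE	10.8	SL
LNT	3	1	0	0	TRUE	12.0	LNT
6'SL	2	0	0	1	TRUE	13.1	SL
LNnT	3	1	0	0	TRUE	14.0	LNT
LNFP I	3	1	1	0	TRUE	15.5	LNFP
LSTa	3	1	0	1	TRUE	16.6	LST
LNFP II	3	1	1	0	TRUE	17.3	LNFP
LSTb	3	1	0	1	TRUE	18.4	LST
LNFP III	3	1	1	0	TRUE	19.1	LNFP
LNDFH I	3	1	2	0	TRUE	20.4	LNDFH
LSTc	3	1	0	1	TRUE	21.2	LST
LNDFH II	3	1	2	0	TRUE	22.3	LNDFH
LNH	4	2	0	0	TRUE	23.8	LNH
DSLNT	3	1	0	2	TRUE	24.5	DSLNT
LNnH	4	2	0	0	TRUE	25.6	LNH
p-LNH	4	2	0	0	TRUE	27.4	LNH
MFpLNH IV	4	2	1	0	TRUE	28.9	MFLNH
S-LNH	4	2	0	1	TRUE	29.8	SLNH
IFLNH III	4	2	1	0	TRUE	30.6	MFLNH
DFLNHa	4	2	2	0	TRUE	31.8	DFLNH
DFpLNH II	4	2	2	0	TRUE	33.5	DFLNH
TFLNH	4	2	3	0	TRUE	34.7	TFLNH
DFLNO I	5	3	2	0	TRUE	36.2	DFLNO
DFLNO II	5	3	2	0	TRUE	38.0	DFLNO
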