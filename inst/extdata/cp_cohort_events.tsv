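case_label	individual_id	sex	cnv_type	location	size_bp	genes	status	aneuploidy_flag	pathogenicity
A	200117	M	dup	Xp22.33-Xq28	155270560	826 genes	De novo	TRUE	Pathogenic
B	234968	F	del	Xq13.1-Xq28	84886227	457 genes	De novo	FALSE	Pathogenic
B	234968	F	dup	Xp22.33-Xq13.1	70384332	369 genes	De novo	FALSE	Pathogenic
C	212306	F	del	Xp22.31	1686421	STS +4 genes	De novo	FALSE	VOUS
C	212306	F	dup	11q24.1	76847	SCN3B,GRAMD1B	Maternal	FALSE	VOUS
C	212306	F	dup	3q11.2	39636	EPHA6	Maternal	FALSE	VOUS
D	208937	F	dup	18p11.23-18p11.31	1146375	LAMA1,PTPRM,LRRC30	De novo	FALSE	VOUS
D	208937	F	dup	Xp21.2	309376	DMD,FTHL17	De novo	FALSE	VOUS
E	216072	F	del	6q16.3	475077	GRIK2	De novo	FALSE	VOUS
F	216185	M	del	10p15.3	67632	DIP2C	De novo	FALSE	VOUS
G	222710	M	del	10p15.3	67632	DIP2C	De novo	FALSE	VOUS
G	222710	M	del	7q36.2	14653	DPP6	Paternal	FALSE	VOUS
G	222710	M	dup	22q11.21	2548820	45 genes	Paternal	FALSE	Likely pathogenic
H	216192	M	del	17p12	1395494	PMP22 +8 genes	Paternal	FALSE	Pathogenic
I	219594	M	del	3p26.3	1027287	CNTN6,CNTN4,CNTN4-AS2	Paternal	FALSE	VOUS
J	198195	M	dup	8p23.1-8p23.2	973229	MCPH1 +10 genes	Maternal	FALSE	VOUS
K	214281	F	dup	5q11.2	504651	HSPB3,ARL15	Maternal	FALSE	VOUS
L	216197	F	dup	16p13.2	370593	ABAT,USP7 +4 genes	Maternal	FALSE	VOUS
M	217737	M	dup	8q24.3	255856	KCNK9	Maternal	FALSE	VOUS
M	217737	M	dup	7q36.3	251267	NCAPG2,ESYT2	Maternal	FALSE	VOUS
N	247947	F	dup	1q23.2	196398	KCNJ10,KCNJ9 +5 genes	Maternal	FALSE	VOUS
O	217932	M	del	3q26.31	176370	NAALADL2	Maternal	FALSE	VOUS
P	208289	F	dup	22q11.21	162405	DGCR2,DGCR14 +4 genes	Maternal	FALSE	VOUS
Q	221713	F	del	7q35	114399	CNTNAP2	Maternal	FALSE	VOUS
R	208341	F	del	5p15.31	77527	SEMA5A	Maternal	FALSE	VOUS
S	234267	F	dup	9q33.1	40814	ASTN2	Paternal	FALSE	VOUS
T	239838	F	del	22q12.3	34122	RFPL2,SLC5A4	Paternal	FALSE	VOUS
U	208290	F	del	18p11.31	25582	DLGAP1	Maternal	FALSE	VOUS
V	199743	F	dup	16q24.3	24064	ZNF778	Maternal	FALSE	VOUS
W	209038	F	dup	17p11.2	16602	MYO15A	Paternal	FALSE	VOUS
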