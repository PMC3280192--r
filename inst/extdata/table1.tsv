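drug	pool_hits	robot_conc_uM	robot_hits	indirect_hits	verification	competitor_protects	lipinski_pass	raw_robot_hits	raw_indirect_hits
Aminopterin		2	NRT1:3;FEN2:3	CTR1:3	partial	not_tested	fail	nrt1D, fen2D	ctr1D
Ammonium pyrrolidine dithiocarbamate		20		PCA1:3	not_tested	not_tested	pass		pca1D
Artesunate		100	FEN2:2	CCH1:2;MID1:2	not_tested	not_tested	pass	fen2D (2*sigma)	cch1D, mid1D (2*sigma)
Bay 11-7085		10	FUI1:3		not_tested	not_tested	pass	fui1D
Benzbromarone	None	28	FUI1:3		not_tested	not_tested	fail	fui1D
Canavanine	CAN1	5	CAN1:3		confirmed	pass	fail	can1D
Cantharidin		30	FEN2:2.5;SNQ2:2.5	CCH1:2.5;MID1:2.5;PHO89:2.5	partial	not_tested	pass	fen2D, snq2D (2.5*sigma)	cch1D, mid1D, pho89D (2.5*sigma)
Cisplatin		50	FCY2:3;LEM3:3;FAT1:2;FPS1:2;HNM1:2		partial	not_tested	pass	fcy2D, lem3D, (fat1D, fps1D, hnm1D 2*sigma)
Clotrimazole		25	ITR1:3	FTR1:3;FET3:3	not_tested	not_tested	fail	itr1D	ftr1D fet3D
3,4-Dichloroisocoumarin		8			not_tested	not_tested	pass	None
Diphenyleneiodonium chloride	NRT1	8	NRT1:3		confirmed	pass	pass	nrt1
Fluconazole		100	ITR1:3;FCY2:3	FTR1:3;FET3:3	not_tested	not_tested	pass	itr1D fcy2D	ftr1D fet3D
5-Fluorocytosine		158	FCY2:3		confirmed	not_tested	pass	fcy2
5-Fluorouracil		158	FCY2:3	FEN2:3	confirmed	not_tested	pass	fcy2D	fen2D
Iodoacetamide		20	MAL11:2.5		solid_only	not_tested	pass	mal11D (2.5*sigma)
Ketoconazole		80	ITR1:3;FAT1:3		not_tested	not_tested	fail	itr1D fat1D
Methotrexate		100	NRT1:3		confirmed	pass	fail	nrt1D
Mitoxantrone		75	AGP1:3		not_tested	not_tested	fail	agp1
1,10-Phenanthroline		14		CTR1:3	not_tested	not_tested	pass		ctr1D
N-Phenylanthranilic acid		100			not_tested	not_tested	pass	None
Protoporphyrin		600	AGP1:3		not_tested	not_tested	fail	agp1D
Tamoxifen		730			not_tested	not_tested	fail	None
Tetraethylthiuram disulfide		10		PDR5:2	not_tested	not_tested	fail		pdr5D (2*sigma)
Tunicamycin		4	LEM3:3;DNF2:3;QDR2:3	PCA1:3;PHO89:3	confirmed	not_tested	fail	lem3D dnf2D qdr2D	pca1D pho89D
Vanillylmandelic acid		647			not_tested	not_tested	pass	None
ZM 39923		14			not_tested	not_tested	fail	None
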