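subunit_name	accession	aliases
α1	P60900	PSMA6;alpha1
α2	P25787	PSMA2;alpha2
α3	P25789	PSMA4;alpha3
α4	O14818	PSMA7;alpha4
α5	P28066	PSMA5;alpha5
α6	P25786	PSMA1;alpha6
α7	P25788	PSMA3;alpha7
β1	P28072	PSMB6;beta1
β2	Q99436	PSMB7;beta2
β3	P49720	PSMB3;beta3
β4	P49721	PSMB2;beta4
β5	P28074	PSMB5;beta5
β6	P20618	PSMB1;beta6
β7	P28070	PSMB4;beta7
β1i	P28065	PSMB9;beta1i
β2i	P40306	PSMB10;beta2i
β5i	P28062	PSMB8;beta5i
Rpt1	P35998	PSMC2
Rpt2	P62191	PSMC1
Rpt3	P43686	PSMC4
Rpt4	P62333	PSMC6
Rpt5	P17980	PSMC3
Rpt6	P62195	PSMC5
Rpn1	Q13200	PSMD2
Rpn2	Q99460	PSMD1
Rpn3	O43242	PSMD3
Rpn5	O00232	PSMD12
Rpn6	O00231	PSMD11
Rpn7	Q15008	PSMD6
Rpn8	P51665	PSMD7
Rpn9	Q9UNM6	PSMD13
Rpn10	P55036	PSMD4
Rpn11	O00487	PSMD14
Rpn12	P48556	PSMD8
Rpn13	Q16186	ADRM1
Rpn14	Q9BRP4	PAAF1
PA28α	Q06323	PSME1;PA28a;PA28alpha
PA28β	Q9UL46	PSME2;PA28b;PA28beta
PA28γ	P61289	PSME3;PA28g;PA28gamma
PA200	Q14997	PSME4
PI31	Q92530	PSMF1
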