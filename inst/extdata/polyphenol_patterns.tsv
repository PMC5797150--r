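pattern_id	smarts	subclasses	class
fla-01	O=c1cc(-c2ccccc2)oc2ccccc12	flavones;flavonols	flavonoids
fla-02	O=c1c(O)c(-c2ccccc2)oc2ccccc12	flavonols	flavonoids
fla-03	O=C1CC(c2ccccc2)Oc2ccccc21	flavanones;dihydroflavonols	flavonoids
fla-04	O=C1C(O)C(c2ccccc2)Oc2ccccc21	dihydroflavonols	flavonoids
fla-05	OC1[CH2]c2ccccc2OC1c1ccccc1	flavanols	flavonoids
fla-06	[o+]1c(-c2ccccc2)ccc2ccccc12	anthocyanins	flavonoids
fla-07	O=[CX3;R0](C=Cc1ccccc1)c1ccccc1	chalcones	flavonoids
fla-08	O=[CX3;R0](CCc1ccccc1)c1ccccc1	dihydrochalcones	flavonoids
fla-09	O=c1c(-c2ccccc2)coc2ccccc12	isoflavonoids	flavonoids
fla-10	C1(c2ccccc2)COc2ccccc2C1	isoflavonoids	flavonoids
fla-11	O=c1oc2ccccc2c2c1c1ccccc1o2	isoflavonoids	flavonoids
fla-12	O[CX4]1[CX4]c2ccccc2O[CX4]1c1ccccc1	flavanols	flavonoids
pha-01	O[CX3;R0](=O)c1ccccc1O	hydroxybenzoic acids	phenolic acids
pha-02	O[CX3;R0](=O)c1cccc(O)c1	hydroxybenzoic acids	phenolic acids
pha-03	O[CX3;R0](=O)c1ccc(O)cc1	hydroxybenzoic acids	phenolic acids
pha-04	O[CX3;R0](=O)C=Cc1ccccc1O	hydroxycinnamic acids	phenolic acids
pha-05	O[CX3;R0](=O)C=Cc1cccc(O)c1	hydroxycinnamic acids	phenolic acids
pha-06	O[CX3;R0](=O)C=Cc1ccc(O)cc1	hydroxycinnamic acids	phenolic acids
pha-07	O[CX3;R0](=O)Cc1ccccc1O	hydroxyphenylacetic acids	phenolic acids
pha-08	O[CX3;R0](=O)Cc1cccc(O)c1	hydroxyphenylacetic acids	phenolic acids
pha-09	O[CX3;R0](=O)Cc1ccc(O)cc1	hydroxyphenylacetic acids	phenolic acids
pha-10	O[CX3;R0](=O)CCc1ccccc1O	hydroxyphenylpropanoic acids	phenolic acids
pha-11	O[CX3;R0](=O)CCc1cccc(O)c1	hydroxyphenylpropanoic acids	phenolic acids
pha-12	O[CX3;R0](=O)CCc1ccc(O)cc1	hydroxyphenylpropanoic acids	phenolic acids
pha-13	O[CX3;R0](=O)CCCCc1ccc(O)cc1	hydroxyphenylpentanoic acids	phenolic acids
lig-01	c1ccccc1C[CX4][CX4]Cc1ccccc1	lignans	lignans
lig-02	c1ccccc1C1OCC2C1COC2c1ccccc1	lignans	lignans
sti-01	c1ccccc1C=Cc1ccccc1	stilbenes	stilbenes
oth-01	[OX2H][CH2][CH2]c1ccc(O)cc1	tyrosols	other polyphenols
oth-02	[CX3H1](=O)c1ccc(O)cc1	hydroxybenzaldehydes	other polyphenols
oth-03	[CX3H1](=O)C=Cc1ccc(O)cc1	hydroxycinnamaldehydes	other polyphenols
oth-04	[#6;!$([#6]=O)][CX3;R0](=O)c1ccc(O)cc1	hydroxybenzoketones	other polyphenols
oth-05	O=c1ccc2ccccc2o1	hydroxycoumarins	other polyphenols
oth-06	O=c1ccc2cc3ccoc3cc2o1	furanocoumarins	other polyphenols
oth-07	O=[CX3;R0](C=Cc1ccccc1)CC(=O)C=Cc1ccccc1	curcuminoids	other polyphenols
oth-08	[CX3]=[CX3][CX4]c1ccc(O)cc1	hydroxyphenylpropenes	other polyphenols
oth-09	COc1ccccc1O	methoxyphenols	other polyphenols
oth-10	[CX4]c1ccc(O)c(OC)c1	alkylmethoxyphenols	other polyphenols
oth-11	[CH2][CH2][CH2]c1cc(O)cc(O)c1	alkylphenols	other polyphenols
oth-12	O=C1C=CC(=O)c2ccccc21	naphtoquinones	other polyphenols
oth-13	[$(C(C)(C)c1ccc(C)cc1O),$(C(C)(C)c1ccc(C)c(O)c1)]	phenolic terpenes	other polyphenols
oth-14	Oc1ccccc1O	catechols	other polyphenols
oth-15	Oc1cc(O)cc(O)c1	other polyphenols	other polyphenols
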