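O	water
CO	methanol
CCO	ethanol
CC(C)O	isopropanol
CCCO	n-propanol
CCCCO	n-butanol
CC(=O)C	acetone
CCC(C)=O	butanone
CC#N	acetonitrile
CS(C)=O	dimethyl_sulfoxide
CN(C)C=O	dimethylformamide
CN(C)C(C)=O	dimethylacetamide
C1CCOC1	tetrahydrofuran
C1COCCO1	1,4-dioxane
CCOCC	diethyl_ether
COC(C)(C)C	methyl_tert-butyl_ether
CCOC(C)=O	ethyl_acetate
COC(C)=O	methyl_acetate
ClCCl	dichloromethane
ClC(Cl)Cl	chloroform
ClC(Cl)(Cl)Cl	tetrachloromethane
CCCCCC	n-hexane
CCCCCCC	n-heptane
CCCCC	n-pentane
C1CCCCC1	cyclohexane
Cc1ccccc1	toluene
c1ccccc1	benzene
Clc1ccccc1	chlorobenzene
Cc1ccccc1C	o-xylene
CC(C)=O	acetone_dup
CC(O)C	isopropanol_dup
N#Cc1ccccc1	benzonitrile
CCCCCCCC	n-octane
OCCO	ethylene_glycol
OCC(O)CO	glycerol
C(=O)O	formic_acid
CC(=O)O	acetic_acid
CN1CCCC1=O	n-methylpyrrolidone
CCCC#N	butyronitrile
COCCOC	dimethoxyethane
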