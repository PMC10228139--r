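# Chain-dominated molecules: alkanes, alcohols, acids, esters, amines,
# ethers, alkenes, alkynes, thiols, nitriles, halides
CC ethane
CCC propane
CCCC butane
CCCCC pentane
CCCCCC hexane
CCCCCCC heptane
CCCCCCCCC nonane
CCCCCCCCCC decane
CCCCCCCCCCCC dodecane
CO methanol
CCO ethanol
CCCO 1-propanol
CCCCO 1-butanol
CCCCCCO 1-hexanol
CCCCCCCCO 1-octanol
OCCO ethylene-glycol
OCC(O)CO glycerol
C=C ethene
CC=C propene
CC=CC 2-butene
C=CCC=C 1,4-pentadiene
C#C ethyne
CC#C propyne
C#N hydrogen-cyanide
CC#N acetonitrile
CCCC#N butyronitrile
C=O formaldehyde
CC=O acetaldehyde
CCC=O propanal
CC(C)=O acetone
OC=O formic-acid
CC(=O)O acetic-acid
CCC(=O)O propionic-acid
CCCCCC(=O)O hexanoic-acid
COC dimethyl-ether
CCOCC diethyl-ether
CC(=O)OC methyl-acetate
CC(=O)OCC ethyl-acetate
CN methylamine
CCN ethylamine
CCCN propylamine
CNC dimethylamine
CN(C)C trimethylamine
CS methanethiol
CCS ethanethiol
CSC dimethyl-sulfide
CSSC dimethyl-disulfide
CCl chloromethane
CCBr bromoethane
CCI iodoethane
CC(F)(F)F 1,1,1-trifluoroethane
ClCCCl 1,2-dichloroethane
NCCO ethanolamine
NCCN ethylenediamine
OCC=O glycolaldehyde
CC(=O)N acetamide
CCCCCCCC=O octanal
CCCCCC=C 1-heptene
CCCCC#C 1-hexyne
CCCCCCCCN 1-octanamine
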