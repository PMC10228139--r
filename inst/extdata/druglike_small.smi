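# Small organic drug-like molecules
CC(=O)Oc1ccccc1C(=O)O aspirin
CC(=O)Nc1ccc(O)cc1 paracetamol
CC(C)Cc1ccc(C(C)C(=O)O)cc1 ibuprofen
COc1ccc2cc([C@@H](C)C(=O)O)ccc2c1 naproxen
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
Cn1cnc2c1c(=O)[nH]c(=O)n2C theobromine-like
CN1CCC[C@H]1c1cccnc1 nicotine
CC(=O)Nc1ccccc1 acetanilide
OC(=O)c1ccccc1O salicylic-acid
COC(=O)c1ccccc1O methyl-salicylate
CN(C)C(=N)N=C(N)N metformin
NC(=O)c1ccncc1 isonicotinamide
NC(=O)c1cccnc1 nicotinamide
OC(=O)c1cccnc1 niacin
Nc1ccc(S(=O)(=O)N)cc1 sulfanilamide
CCN(CC)CC(=O)Nc1c(C)cccc1C lidocaine
CC(N)Cc1ccccc1 amphetamine
CNC(C)Cc1ccccc1 methamphetamine
CC(CN)O alaninol-like
N[C@@H](C)C(=O)O L-alanine
N[C@@H](CC(=O)O)C(=O)O L-aspartic-acid
N[C@@H](CO)C(=O)O L-serine
N[C@@H](Cc1ccccc1)C(=O)O L-phenylalanine
N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O L-tryptophan
NCC(=O)O glycine
OC(=O)CC(O)(CC(=O)O)C(=O)O citric-acid
OC(=O)C(O)C(O)C(=O)O tartaric-acid
OC(=O)C=CC(=O)O fumaric-acid
OC(=O)CCC(=O)O succinic-acid
CC(O)C(=O)O lactic-acid
OCC1OC(O)C(O)C(O)C1O glucose-ring
OC[C@H]1O[C@@H](O)[C@H](O)[C@@H](O)[C@@H]1O alpha-D-glucopyranose
Oc1ccc(CCN)cc1 tyramine-like
NCCc1c[nH]c2ccccc12 tryptamine
NCCc1ccc(O)c(O)c1 dopamine
CNC[C@H](O)c1ccc(O)c(O)c1 epinephrine
NC[C@H](O)c1ccc(O)c(O)c1 norepinephrine
CNC[C@H](O)c1cccc(O)c1 phenylephrine-like
CC(C)NCC(O)COc1ccc2ccccc2c1 propranolol-like
CC(C)NC[C@H](O)c1ccc(O)c(O)c1 isoprenaline
NC(=O)N urea
NC(=O)NC(=O)N biuret-like
O=c1[nH]cnc2[nH]cnc12 hypoxanthine
O=c1[nH]c(=O)c2[nH]cnc2[nH]1 xanthine-like
Nc1ncnc2[nH]cnc12 adenine
Nc1nc2[nH]cnc2c(=O)[nH]1 guanine
Cc1cc(=O)[nH]c(=O)[nH]1 6-methyluracil
O=c1cc[nH]c(=O)[nH]1 uracil
Cc1c[nH]c(=O)[nH]c1=O thymine
Nc1cc[nH]c(=O)n1 cytosine
Oc1ccc2ccccc2c1 2-naphthol
COc1ccccc1 anisole
CCOC(=O)c1ccccc1N benzocaine
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O warfarin
Clc1ccccc1C(=O)Nc1ccccc1 chlorobenzanilide-like
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
COc1cc2c(cc1OC)CCN(C)C2 dimethoxy-thiq-like
CN1C2CCC1CC(OC(=O)C(CO)c1ccccc1)C2 atropine
CCN(CC)C(=O)c1cc(C)cc(C)c1 diethyl-dimethylbenzamide
COc1ccc(CCN(C)C)cc1 methoxyphenethylamine-like
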