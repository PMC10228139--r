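# Ring systems: carbo/heteroaromatics, fused, saturated, spiro, bridged
c1ccccc1 benzene
Cc1ccccc1 toluene
c1ccncc1 pyridine
c1ccc[nH]1 pyrrole
c1ccoc1 furan
c1ccsc1 thiophene
c1c[nH]cn1 imidazole
c1cc[nH]n1 pyrazole
c1cnco1 oxazole
c1cncs1 thiazole
c1cnccn1 pyrazine
c1ccnnc1 pyridazine
c1cncnc1 pyrimidine
c1cnc2[nH]cnc2n1 purine
c1ccc2ccccc2c1 naphthalene
c1ccc2ncccc2c1 quinoline
c1ccc2cnccc2c1 isoquinoline
c1ccc2[nH]ccc2c1 indole
c1ccc2occc2c1 benzofuran
c1ccc2sccc2c1 benzothiophene
c1ccc2[nH]cnc2c1 benzimidazole
c1ccc2nonc2c1 benzofurazan
c1ccc(-c2ccccc2)cc1 biphenyl
C1CC1 cyclopropane
C1CCC1 cyclobutane
C1CCCC1 cyclopentane
C1CCCCC1 cyclohexane
C1CCCCCC1 cycloheptane
C1CCOC1 tetrahydrofuran
C1CCOCC1 oxane
C1COCCO1 1,4-dioxane
C1CCNC1 pyrrolidine
C1CCNCC1 piperidine
C1CNCCN1 piperazine
C1COCCN1 morpholine
C1CSCCS1 1,3-dithiane-like
C1CC2CCC1C2 norbornane
C1CC2CCC(C1)C2 bicyclo[2.2.2]octane-like
C1CC2(CC1)CCCC2 spiro[4.4]nonane
C1CCC2(CC1)CCCCC2 spiro[5.5]undecane
O=[N+]([O-])c1ccccc1 nitrobenzene
Clc1csc2nc3ncncn3c12 fused-azine-probe-a
Clc1csc2nc3nnccn3c12 fused-azine-probe-b
Oc1ccccc1 phenol
Nc1ccccc1 aniline
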