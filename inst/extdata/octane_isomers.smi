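# The 18 constitutional isomers of C8H18
CCCCCCCC octane
CC(C)CCCCC 2-methylheptane
CCC(C)CCCC 3-methylheptane
CCCC(C)CCC 4-methylheptane
CC(C)(C)CCCC 2,2-dimethylhexane
CC(C)C(C)CCC 2,3-dimethylhexane
CC(C)CC(C)CC 2,4-dimethylhexane
CC(C)CCC(C)C 2,5-dimethylhexane
CCC(C)(C)CCC 3,3-dimethylhexane
CCC(C)C(C)CC 3,4-dimethylhexane
CCC(CC)CCC 3-ethylhexane
CC(C)(C)C(C)CC 2,2,3-trimethylpentane
CC(C)(C)CC(C)C 2,2,4-trimethylpentane
CCC(C)(C)C(C)C 2,3,3-trimethylpentane
CC(C)C(C)C(C)C 2,3,4-trimethylpentane
CCC(CC)C(C)C 3-ethyl-2-methylpentane
CCC(C)(CC)CC 3-ethyl-3-methylpentane
CC(C)(C)C(C)(C)C 2,2,3,3-tetramethylbutane
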