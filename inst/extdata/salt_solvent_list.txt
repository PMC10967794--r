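# Common counterions and solvents removed during structure standardization.
# One SMILES per line; matched against neutralized, stereo-free canonical
# component forms. Carbon-free components are always removed regardless of
# this list.
CC(=O)O        # acetic acid / acetate
C(=O)O         # formic acid / formate
OC(=O)C(=O)O   # oxalic acid
CS(=O)(=O)O    # methanesulfonic acid (mesylate)
Cc1ccc(cc1)S(=O)(=O)O  # p-toluenesulfonic acid (tosylate)
OC(=O)C(O)C(O)C(=O)O   # tartaric acid
OC(=O)CC(O)(CC(=O)O)C(=O)O  # citric acid
OC(=O)C=CC(=O)O  # fumaric/maleic acid (stereo-free)
CCO            # ethanol
CO             # methanol
CC(C)O         # isopropanol
CC(=O)C        # acetone
C1CCOC1        # tetrahydrofuran
CS(=O)C        # DMSO
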