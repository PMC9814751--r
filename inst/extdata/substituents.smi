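# Small commercially available substituents (SMILES id)
CN methylamine
CCN ethylamine
CCCCN butylamine
CNC dimethylamine
Nc1ccccc1 aniline
NCCO ethanolamine
NCc1ccccc1 benzylamine
CO methanol
CCO ethanol
CC(C)O isopropanol
CCCCO butanol
OCCO ethylene_glycol
OCc1ccccc1 benzyl_alcohol
OCCOC methoxyethanol
CI methyl_iodide
CCBr ethyl_bromide
CCCCBr butyl_bromide
ClCc1ccccc1 benzyl_chloride
C=CCBr allyl_bromide
BrCCCCCCCCCCCCCCCCCC octadecyl_bromide
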