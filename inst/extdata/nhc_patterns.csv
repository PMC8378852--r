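# NHC ligand substructure patterns, one per line, in the package's
# SMILES-fragment dialect (matched as colored subgraph monomorphisms;
# hydrogen counts are not constrained).
# imidazol-2-ylidene (free carbene)
[C]1[N][CH]=[CH][N]1
# imidazolin-2-ylidene (saturated free carbene)
[C]1[N][CH2][CH2][N]1
# imidazolium (aromatic azolium precursor)
[c]1[n+][c][c][n]1
# imidazolinium (saturated azolium precursor)
[CH]1=[N+][CH2][CH2][N]1
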