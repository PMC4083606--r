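# Illustrative helix selection for an MHC class I heavy chain.
# The residue ranges below are typical of the alpha1/alpha2 groove helices in
# HLA class I author numbering but MUST be adapted to the structure at hand
# (e.g. after checking the secondary-structure annotation of your PDB entry);
# they are an example of the file format, not a validated assignment.
helices:
  G-ALPHA1: {chain: A, first_residue: 57, last_residue: 84}
  G-ALPHA2: {chain: A, first_residue: 138, last_residue: 175}
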