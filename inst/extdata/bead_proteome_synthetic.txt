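# Synthetic bead-proteome reference list (matrix-binding contaminants)
# One accession per line; matches the default synthetic experiment.
BEAD_0001
BEAD_0002
BEAD_0003
BEAD_0004
BEAD_0005
BEAD_0006
BEAD_0007
BEAD_0008
BEAD_0009
BEAD_0010
BEAD_0011
BEAD_0012
BEAD_0013
BEAD_0014
BEAD_0015
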