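# Arginine-anchor residue specifications for selectResidueSet().
# One row per anchor: histone type, expected one-letter amino acid, seqid.
# Anchor identities vary between structures; fill in per system.
# Shipped empty by default.
histone	aa	seqid
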