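name: uag_reporter_synthetic
stall_offset: 120
orphan_codon: TAG
tag_variant: DD
anchor_peptide: LEHHHHHH
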