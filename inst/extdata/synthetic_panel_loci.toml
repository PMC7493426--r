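[L01]
motif_length = 2
reference_offset = 0

[L02]
motif_length = 4
reference_offset = 0

[L03]
motif_length = 2
reference_offset = 0

[L04]
motif_length = 4
reference_offset = 0

[L05]
motif_length = 2
reference_offset = 0

[L06]
motif_length = 4
reference_offset = 0

[L07]
motif_length = 2
reference_offset = 0

[L08]
motif_length = 4
reference_offset = 0

[L09]
motif_length = 2
reference_offset = 0

[L10]
motif_length = 4
reference_offset = 0

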