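edge_repeat=TGCAGTGCCA
loop_repeat=TGAAACCA
spacer_len_a=9
spacer_len_b=9
processing_offset=5
enforce_boxes=TRUE
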