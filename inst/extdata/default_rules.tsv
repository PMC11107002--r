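pattern	call
lineage B + lineage G	lineage G
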