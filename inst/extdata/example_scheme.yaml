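"N": noncoding
"C1": forward_gene
"C2": forward_gene
"C3": forward_gene
"R1": reverse_gene
"R2": reverse_gene
"R3": reverse_gene
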