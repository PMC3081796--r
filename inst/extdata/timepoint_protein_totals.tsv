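timepoint	n_proteins
4h	818
1d	928
3d	978
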