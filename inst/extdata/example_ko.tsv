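gene1	K02777
gene2	K03407
gene3
gene4	K00844
gene5
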