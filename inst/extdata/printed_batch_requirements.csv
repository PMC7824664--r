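rna_per_dose,titre,volume,batches
100,4,30,13544
100,6,30,9030
0.1,6,1,271
0.1,4,1,407
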