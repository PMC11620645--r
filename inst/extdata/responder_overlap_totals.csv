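quantity,count
spatio_responders,616
genotype_responders,129
both_responders,103
gene_universe,6575
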