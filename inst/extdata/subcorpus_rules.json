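[{"label":"Genetics","pattern":"[Gg]enet"},{"label":"Genomics","pattern":"[Gg]enom"},{"label":"Medicine","pattern":"[Mm]edicin"}]
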