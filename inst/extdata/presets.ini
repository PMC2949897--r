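# Example preset file. Each [section] defines one delimited-file dialect;
# keys are the column_preset fields. Built-in presets (genepool,
# plink_assoc, eigenstrat) are always available in addition.

[generic_pvalue]
header_mode = auto
delimiter_policy = any_whitespace
chrom_col = 1
pos_col = 2
id_col = 3
value_col = 4
value_kind = pvalue
max_expected = 8

[rank_table]
header_mode = no
delimiter_policy = tab
chrom_col = 2
pos_col = 3
id_col = 1
value_col = 4
value_kind = rank
max_expected = 100
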