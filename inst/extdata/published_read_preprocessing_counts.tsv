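accession	stage	count
acc1644	raw_reads	1338956
acc1644	clipped_reads	1155
acc1644	short_reads	62233
acc1644	triticeae_repeats	10850
acc1644	organelle	16586
acc1644	human_repeats	459
acc2232	raw_reads	1355371
acc2232	clipped_reads	853
acc2232	short_reads	54918
acc2232	triticeae_repeats	9001
acc2232	organelle	9427
acc2232	human_repeats	260
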