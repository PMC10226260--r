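chromosome	n_genes	n_hits
chr1	2048	22
chr2	1247	17
chr3	1075	4
chr4	751	5
chr5	886	4
chr6	1047	6
chr7	917	4
chr8	683	3
chr9	781	5
chr10	731	4
chr11	1311	6
chr12	1035	10
chr13	321	3
chr14	612	0
chr15	599	7
chr16	853	5
chr17	1188	52
chr18	268	3
chr19	1471	9
chr20	546	2
chr21	232	0
chr22	444	4
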