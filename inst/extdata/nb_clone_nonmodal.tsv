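line	sample	sample_type	probe	modal_n	nonmodal_pct
Fibroblasts	control	control	CEP11	2	0.5
Fibroblasts	control	control	CEP17	2	0
Fibroblasts	control	control	CEP18	2	0
Fibroblasts	control	control	1p	2	0
Fibroblasts	control	control	17q	2	0
GI-MEN	mother	mother	CEP11	2	51
GI-MEN	mother	mother	CEP17	2	36
GI-MEN	mother	mother	CEP18	3	23
GI-MEN	mother	mother	1p	2	8
GI-MEN	mother	mother	17q	2	48
GI-MEN	F5	clone	CEP11	5	8
GI-MEN	F5	clone	CEP17	2	5
GI-MEN	F5	clone	CEP18	2	12
GI-MEN	F5	clone	1p	2	5
GI-MEN	F5	clone	17q	5	34
GI-MEN	A9	clone	CEP11	6	30
GI-MEN	A9	clone	CEP17	2	9
GI-MEN	A9	clone	CEP18	4	23
GI-MEN	A9	clone	1p	2	18
GI-MEN	A9	clone	17q	6	43
GI-MEN	D3	clone	CEP11	5	5
GI-MEN	D3	clone	CEP17	2	12
GI-MEN	D3	clone	CEP18	4	21
GI-MEN	D3	clone	1p	2	1
GI-MEN	D3	clone	17q	5	42
SK-N-AS	mother	mother	CEP11	2	14
SK-N-AS	mother	mother	CEP17	1	26
SK-N-AS	mother	mother	CEP18	3	32
SK-N-AS	mother	mother	1p	2	16
SK-N-AS	mother	mother	17q	4	73
SK-N-AS	C8	clone	CEP11	2	11
SK-N-AS	C8	clone	CEP17	1	6
SK-N-AS	C8	clone	CEP18	2	13
SK-N-AS	C8	clone	1p	2	10
SK-N-AS	C8	clone	17q	4	66
SK-N-AS	E7	clone	CEP11	2	5
SK-N-AS	E7	clone	CEP17	1	6
SK-N-AS	E7	clone	CEP18	2	8
SK-N-AS	E7	clone	1p	2	12
SK-N-AS	E7	clone	17q	4	50
SK-N-AS	C5	clone	CEP11	2	5
SK-N-AS	C5	clone	CEP17	1	6
SK-N-AS	C5	clone	CEP18	2	8
SK-N-AS	C5	clone	1p	2	12
SK-N-AS	C5	clone	17q	4	50
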