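variable	category	score	count
Ki67	0-10%	0	5
Ki67	0-10%	1	48
Ki67	0-10%	2	33
Ki67	0-10%	3	7
Ki67	11-100%	0	3
Ki67	11-100%	1	29
Ki67	11-100%	2	68
Ki67	11-100%	3	53
Ki67	unknown	0	1
Ki67	unknown	1	0
Ki67	unknown	2	4
Ki67	unknown	3	1
grade	I	0	4
grade	I	1	25
grade	I	2	23
grade	I	3	4
grade	II	0	5
grade	II	1	42
grade	II	2	38
grade	II	3	19
grade	III	0	0
grade	III	1	9
grade	III	2	44
grade	III	3	38
nodal	N0	0	4
nodal	N0	1	45
nodal	N0	2	49
nodal	N0	3	41
nodal	N1+	0	2
nodal	N1+	1	21
nodal	N1+	2	47
nodal	N1+	3	15
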