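chr7	55259515	T	G
chr7	55249071	C	T
chr12	25398284	C	T
chr7	140453136	A	T
chr3	178936091	G	A
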