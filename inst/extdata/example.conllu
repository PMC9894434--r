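# text = My neighbour has a black cat
1	My	my	PRON	ppron12:sg:nom	_	2	nmod	_	_
2	neighbour	neighbour	NOUN	subst:sg:nom	_	3	nsubj	_	_
3	has	have	VERB	fin:sg:ter	_	0	root	_	_
4	a	a	DET	adj:sg:nom	_	6	det	_	_
5	black	black	ADJ	adj:sg:nom	_	6	amod	_	_
6	cat	cat	NOUN	subst:sg:acc	_	3	obj	_	_
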