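snp_id	position	state	aa	rsa	asa	z_fit	class
rs121965021	533	native	P	0.341	48.43	-1.149	Buried
rs121965021	533	mutant	R	0.344	78.73	-0.651	Buried
rs371397270	349	native	D	0.241	34.699	-0.488	Buried
rs371397270	349	mutant	G	0.392	30.819	-1.405	Exposed
rs775816150	374	native	T	0.095	13.149	-1.852	Buried
rs775816150	374	mutant	P	0.233	33.134	-1.134	Buried
rs772416503	496	native	P	0.105	14.928	0.247	Buried
rs772416503	496	mutant	R	0.164	37.533	-0.253	Buried
rs121965033	346	native	L	0.031	5.603	0.342	Buried
rs121965033	346	mutant	R	0.108	24.09	-0.954	Buried
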