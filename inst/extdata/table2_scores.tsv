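snp_id	mutation	phdsnp_label	phdsnp_p	panther_label	panther_p	snpsgo_label	snpsgo_p
rs76722191	V322E	Disease	0.718	Disease	0.712	Disease	0.716
rs121965021	P533R	Disease	0.635	Disease	0.827	Disease	0.671
rs121965029	R89Q	Disease	0.841	Disease	0.609	Disease	0.745
rs121965033	L346R	Disease	0.76	Disease	0.792	Disease	0.663
rs148789453	L238Q	Disease	0.777	Disease	0.553	Disease	0.513
rs200448421	R628P	Disease	0.817	Disease	0.529	Disease	0.634
rs368454909	D349N	Disease	0.723	Disease	0.603	Disease	0.54
rs369090960	G265R	Disease	0.12	Disease	0.841	Disease	0.63
rs371397270	D349G	Disease	0.754	Disease	0.663	Disease	0.593
rs373037758	L256P	Disease	0.881	Disease	0.795	Disease	0.801
rs374779600	P533S	Disease	0.539	Disease	0.718	Disease	0.579
rs587779401	Y625C	Disease	0.722	Disease	0.867	Disease	0.724
rs748239393	F287C	Disease	0.668	Disease	0.862	Disease	0.628
rs750496798	R363C	Disease	0.764	Disease	0.903	Disease	0.701
rs753308650	G168R	Disease	0.91	Disease	0.841	Disease	0.846
rs754154200	E182K	Disease	0.772	Disease	0.591	Disease	0.702
rs754876066	T194P	Disease	0.747	Disease	0.732	Disease	0.628
rs757706461	P183S	Disease	0.619	Disease	0.718	Disease	0.602
rs762623046	R166T	Disease	0.739	Disease	0.547	Disease	0.639
rs772416503	P496R	Disease	0.606	Disease	0.827	Disease	0.568
rs773908263	P81S	Disease	0.725	Disease	0.688	Disease	0.667
rs775542391	L114R	Disease	0.818	Disease	0.786	Disease	0.743
rs775816150	T374P	Disease	0.771	Disease	0.732	Disease	0.538
rs780165694	Y76C	Disease	0.646	Disease	0.703	Disease	0.522
rs794726877	G51D	Disease	0.74	Disease	0.79	Disease	0.704
rs875989946	W175R	Disease	0.866	Disease	0.839	Disease	0.831
rs767140903	P302R	Disease	0.673	Disease	0.827	Disease	0.678
rs375819348	P493R	Disease	0.681	Disease	0.827	Disease	0.633
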