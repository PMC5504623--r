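chrom	p	rho0	region_starts	region_lengths
chr01	595	0.091	55,157,231	20,5,8
chr02	842	0.171	22,63,161,276,420,515	7,20,7,40,5,8
chr03	682	0.108	33,130,191	7,3,20
chr04	510	0.234	39,145,198,318,390	6,10,30,10,5
chr05	872	0.171	26,152,247	40,20,30
chr06	522	0.174	44,163,282,338,457	15,7,15,4,30
chr07	599	0.125	41,151,214,324	8,30,3,15
chr08	420	0.277	38,153,208,316	6,9,40,6
chr09	644	0.226	35,155,250	30,7,4
chr10	452	0.07	34,176,274	30,3,5
chr11	466	0.275	40,98,150,259	20,4,4,15
chr12	714	0.212	53,198,312,437,502,625	30,3,6,4,9,3
chr13	718	0.247	32,80,188	7,40,30
chr14	505	0.172	51,157,285,407	30,20,30,20
chr15	699	0.233	55,115,204,270	5,5,3,7
chr16	344	0.108	28,114,233	7,10,20
chr17	873	0.104	20,107,170,242	20,5,5,15
chr18	779	0.253	44,144,260	6,5,3
chr19	340	0.139	52,114,228	3,5,4
chr20	708	0.181	44,121,181	4,15,40
chr21	762	0.097	43,129,236	20,10,4
chr22	877	0.185	29,149,271,310	15,6,8,3
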