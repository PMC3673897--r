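library	total_reads	high_quality_reads	too_short_reads	clean_reads	mapped_clean_reads	unique_tags	mapped_unique_tags
HPL	22925183	22643245	126772	22483373	18248364	2901995	2396442
LPL	26658394	26377550	68893	26268210	22176679	3951946	3301579
HPR	21456069	20957370	347577	20564547	15573680	4071174	2360847
LPR	28635677	27944092	800247	27083979	20591098	4641188	2583592
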