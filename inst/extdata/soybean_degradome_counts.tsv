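field	count
high_quality_reads	28557354
clean_reads	25241382
mapped_clean_reads	21185857
unique_reads	3553894
mapped_unique_reads	2406610
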