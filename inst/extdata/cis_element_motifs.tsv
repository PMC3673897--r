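name	pattern	strands
P1BS	GNATATNC	both
W-box	TTGACY	both
TATA-box	TATAWAW	both
TSS	TTCANTYY	sense
PHO	CACGTG	both
PHO-like	CACGTC	both
NIT2	TATCTA	both
TC	TTCTTCTC	both
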