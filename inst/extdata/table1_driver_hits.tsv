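gene	chrom	pos	ref	alt	consequence	subline	clinvar_id	vaf
ABL1	chr9	130873012	C	A	missense	lowN-R1		0.2648
AR	chrX	67545735	C	A	missense	highIM-R3		0.4655
BIRC6	chr2	32482454	A	G	missense	highIM-R4		0.2222
CACNA1D	chr3	53811368	G	T	missense	lowIM-R3		0.3429
CACNA1D	chr3	53811368	G	T	missense	lowIM-R4		0.4444
CREBBP	chr16	3728619	A	G	missense	lowN-R1		0.4066
EML4	chr2	42303119	G	A	missense	highIM-R4		0.3333
FAT3	chr11	92799273	T	A	missense	lowIM-R4		0.2526
IKBKB	chr8	42322352	C	T	missense	highIM-R1		0.5152
KAT6A	chr8	41932591	G	A	missense	highIM-R1		0.3967
KAT6A	chr8	41932591	G	A	missense	lowIM-R4		0.2611
KAT6A	chr8	41932591	G	A	missense	lowN-R2		0.4081
KLF5	chr13	73062263	C	G	missense	lowIM-R1		0.3077
KMT2D	chr12	49041444	T	A	missense	highN-R1		0.2481
KMT2D	chr12	49037560	G	C	missense	lowIM-R3		0.2043
KMT2D	chr12	49037560	G	C	missense	lowIM-R4		0.2875
KMT2D	chr12	49054080	G	A	missense	highIM-R3	449928	0.371
KRAS	chr12	25227349	C	T	missense	highIM-R3	12581	0.6667
KRAS	chr12	25245350	C	T	missense	highIM-R4	12582	0.2927
LATS2	chr13	20988621	C	G	missense	lowN-R1		0.4286
LRP1B	chr2	140487651	A	T	missense	highIM-R1		0.3881
LRP1B	chr2	140598785	G	A	missense	highIM-R1		0.304
MAP2	chr2	209710175	A	G	missense	highN-R1		0.3333
MAP3K1	chr5	56882018	A	G	missense	lowN-R1		0.1667
MB21D2	chr3	192917686	T	A	missense	highN-R1		0.5682
MCM3AP	chr21	46270451	G	A	stop_gain	lowIM-R1		0.25
MYH9	chr22	36327477	G	C	missense	highN-R1		0.381
NRAS	chr1	114713909	C	A	missense	lowN-R2	73058	0.2917
NRAS	chr1	114713909	C	A	missense	highN-R2	73058	0.3333
PDE4DIP	chr1	149009789	C	T	missense	lowN-R2		0.3
PDE4DIP	chr1	149009789	C	T	missense	highN-R2		0.1961
PDGFRB	chr5	150125520	G	C	missense	highIM-R2		0.283
PRKCB	chr16	24113032	G	A	missense	highIM-R3		0.5152
PTPN11	chr12	112473023	A	G	missense	highIM-R2	13328	0.6929
RELA	chr11	65660125	T	A	missense	lowIM-R2		0.2828
RELA	chr11	65660125	T	A	missense	highIM-R2		0.2923
SALL4	chr20	51791491	G	C	missense	highIM-R1		0.4322
SOX9	chr17	72122970	C	T	missense	highIM-R1		0.3066
TNC	chr9	115081787	T	C	missense	lowIM-R2		0.2
TNC	chr9	115081787	T	C	missense	highIM-R2		0.2222
TP63	chr3	189737766	C	T	missense	lowIM-R1		0.4909
TP63	chr3	189889387	C	A	missense	highN-R1		0.1538
TRRAP	chr7	98955211	G	A	missense	lowN-R2		0.2993
TRRAP	chr7	98955211	G	A	missense	highN-R2		0.2685
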