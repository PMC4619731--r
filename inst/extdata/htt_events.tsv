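locus	fig_label	gap_start	gap_end	as_type	read_support
chr4:3122657-3125708	A	3122936	3124249	Acceptor	13
chr4:3122657-3125708	A	3122936	3125548	Canonical	1075
chr4:3129985-3130317	B	3129999	3130304	Donor	10
chr4:3129985-3130317	B	3130047	3130304	Canonical	874
chr4:3147882-3160569	C	3148207	3160281	Skipped Exon	21
chr4:3147882-3160569	C	3148207	3154292	Canonical	1574
chr4:3172847-3174849	D	3173131	3174720	Canonical	1619
chr4:3172847-3174849	D	3173218	3174720	Donor	23
chr4:3172847-3174849	D	3173331	3174720	Donor	10
chr4:3188868-3204258	E	3189093	3199731	Canonical	2998
chr4:3188868-3204258	E	3189093	3204006	Skipped Exon	32
chr4:3188868-3204258	E	3199939	3202976	Added Exon	194
chr4:3188868-3204258	E	3199939	3202981	Added Exon	34
chr4:3188868-3204258	E	3199939	3204006	Canonical	3069
chr4:3188868-3204258	E	3199939	3204009	Acceptor	20
chr4:3206723-3209011	F	3206983	3207280	Canonical	3962
chr4:3206723-3209011	F	3206983	3207285	Acceptor	246
chr4:3206723-3209011	F	3207357	3208772	Canonical	3995
chr4:3206723-3209011	F	3207357	3208802	Acceptor	23
chr4:3206723-3209011	F	3207466	3208772	Donor	10
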