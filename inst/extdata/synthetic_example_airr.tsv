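junction_aa	v_call	j_call	duplicate_count	productive
CASSLGGNTEAFF	TRBV12-3*01	TRBJ1-1*01	42	T
CASSYSDTGELFF	TRBV6-2	TRBJ2-2*01	17	T
CASSLTGNTEAFF	TRBV12-1	TRBJ1-1	9	T
CASSQGYEQYF	TRBV3-1	TRBJ2-7	5	T
CASSLSGNTIYF	TRBV12-3	TRBJ1-3	3	T
CASSPDRGAYEQYF	TRBV2	TRBJ2-7	2	T
CASRGDSNQPQHF	TRBV19	TRBJ1-5	1	T
CASSFWDRVNTEAFF	TRBV28	TRBJ1-1	1	T
CASSL*GNTEAFF	TRBV12-3	TRBJ1-1	4	F
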