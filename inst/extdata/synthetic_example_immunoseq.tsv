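aminoAcid	vGeneName	jGeneName	count	sequenceStatus
CASSLGGNTEAFF	TRBV12-3*01	TRBJ1-1*01	42	In
CASSYSDTGELFF	TRBV6-2	TRBJ2-2*01	17	In
CASSLTGNTEAFF	TRBV12-1	TRBJ1-1	9	In
CASSQGYEQYF	TRBV3-1	TRBJ2-7	5	In
CASSLSGNTIYF	TRBV12-3	TRBJ1-3	3	In
CASSPDRGAYEQYF	TRBV2	TRBJ2-7	2	In
CASRGDSNQPQHF	TRBV19	TRBJ1-5	1	In
CASSFWDRVNTEAFF	TRBV28	TRBJ1-1	1	In
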