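id	family_ids	saliva_evidence	peptide_count
SP0001	FP001	1	11
SP0002	FP002	1	14
SP0003	FP003	1	12
SP0004	FP001	1	11
SP0005	FP002	1	9
SP0006	FP003	1	11
SN0001	FN001	0	19
SN0002	FN002	0	6
SN0003	FN003	0	8
SN0004	FN001	0	8
SN0005	FN002	0	9
SN0006	FN003	0	4
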