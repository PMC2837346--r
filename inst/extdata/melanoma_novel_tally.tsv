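row	QF1160MB	MELB	MM653	D20	MM386	MM426	MM466	MM603	MM472	D10	D11	MEL202
unique_to_library	33	0	17	21	26	16	10	20	11	4	6	9
present_in_2_or_more	52	16	33	51	64	39	45	40	33	22	27	25
totals	85	16	50	72	90	55	55	60	44	26	33	34
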