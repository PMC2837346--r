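mirna	QF1160MB	MELB	MM653	D20	MM386	MM426	MM466	MM603	MM472	D10	D11	MEL202
hsa-let-7a	2	2	1	2	1	2	3	2	2	2	2	2
hsa-let-7b	5	3	2	3	5	3	NA	4	3	4	5	5
hsa-let-7d	NA	9	NA	NA	NA	NA	NA	8	NA	6	7	7
hsa-let-7e	6	4	8	NA	NA	NA	NA	NA	NA	NA	NA	9
hsa-let-7f	1	1	3	1	3	1	7	1	1	1	1	1
hsa-let-7g	NA	10	NA	NA	NA	10	NA	7	NA	NA	4	8
hsa-let-7i	3	5	10	6	6	NA	NA	NA	9	8	6	NA
hsa-miR-103	10	NA	NA	8	7	6	2	3	6	NA	3	6
hsa-miR-140-3p	NA	NA	NA	NA	NA	NA	NA	NA	4	9	9	10
hsa-miR-146a	NA	NA	NA	NA	NA	8	NA	NA	NA	NA	NA	NA
hsa-miR-181a	NA	NA	NA	NA	10	NA	NA	NA	NA	NA	NA	NA
hsa-miR-185	NA	NA	NA	NA	NA	NA	NA	10	NA	NA	NA	NA
hsa-miR-21	NA	NA	6	5	4	4	8	9	5	NA	NA	NA
hsa-miR-211	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	10	NA
hsa-miR-221	NA	NA	4	7	9	NA	NA	NA	NA	NA	NA	NA
hsa-miR-222	NA	NA	9	NA	NA	NA	NA	NA	NA	NA	NA	NA
hsa-miR-25	NA	NA	NA	NA	NA	9	10	NA	NA	10	8	NA
hsa-miR-29a	9	6	7	4	2	5	1	5	7	3	NA	NA
hsa-miR-320a	4	8	5	9	NA	NA	NA	NA	8	7	NA	3
hsa-miR-378	7	7	NA	10	NA	7	4	NA	NA	5	NA	4
hsa-miR-423-5p	8	NA	NA	NA	8	NA	5	NA	10	NA	NA	NA
hsa-miR-886-5p	NA	NA	NA	NA	NA	NA	6	NA	NA	NA	NA	NA
hsa-miR-92a	NA	NA	NA	NA	NA	NA	9	6	NA	NA	NA	NA
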