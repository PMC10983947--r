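group	min_tr	max_tr	min_cys_before	max_cys_before	central_tr_copies	tr1_min	tr1_max
P1	4	4	3	3	NA	NA	NA
P2	4	4	5	5	NA	NA	26
P3	4	4	5	5	NA	27	NA
P4	5	5	5	5	11	NA	NA
P5	4	4	7	7	NA	NA	NA
P6	5	5	7	7	11	NA	NA
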