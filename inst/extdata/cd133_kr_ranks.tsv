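entity	tf_rank	mr_rank	total_rank
TRIM28	5	5	10
RELA	5	3	8
MYB	4	4	8
CREB1	4	2	6
REST	4	2	6
TP53	4	2	6
CEBPA	3	3	6
GABPB1	3	2	5
NANOG	2	2	4
E2F1	2	2	4
E2F3	2	2	4
E2F4	2	2	4
E2F7	2	2	4
EGR1	2	2	4
HIF1A	2	2	4
HMGA1	2	2	4
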