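genome_id	gene_id	KO
isolate_A	gA_0001	K00844
isolate_A	gA_0002	K01810
isolate_A	gA_0003	K00850
isolate_A	gA_0004	K01623
isolate_A	gA_0005	K01803
isolate_A	gA_0006	K00134
isolate_A	gA_0007	K00927
isolate_A	gA_0008	K01834
isolate_A	gA_0009	K01689
isolate_A	gA_0010	K00873
isolate_A	gA_0011	K01647
isolate_A	gA_0012	K01681
isolate_A	gA_0013	K00031
isolate_A	gA_0014	K00024
isolate_B	gB_0001	K00036
isolate_B	gB_0002	K01690
isolate_B	gB_0003	K01625
isolate_B	gB_0004	K01057
isolate_B	gB_0005	K00033
isolate_B	gB_0006	K00016
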