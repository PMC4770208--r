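id	template_id	true_errors	positions
sim000001	t1	1	60
sim000002	t1	0	
sim000003	t1	0	
sim000004	t1	0	
sim000005	t2	1	96
sim000006	t4	0	
sim000007	t2	0	
sim000008	t2	3	80,85,92
sim000009	t1	0	
sim000010	t4	0	
sim000011	t3	0	
sim000012	t4	0	
sim000013	t3	0	
sim000014	t4	0	
sim000015	t1	0	
sim000016	t1	0	
sim000017	t2	0	
sim000018	t4	0	
sim000019	t2	1	86
sim000020	t2	0	
sim000021	t3	1	98
sim000022	t3	0	
sim000023	t1	0	
sim000024	t1	0	
sim000025	t3	0	
sim000026	t4	0	
sim000027	t1	0	
sim000028	t3	1	97
sim000029	t1	0	
sim000030	t1	0	
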