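node	type	module
t001	target	1
t002	target	1
t003	target	1
t004	target	1
t005	target	1
t006	target	1
t007	target	1
t008	target	1
t009	target	1
t010	target	1
t011	target	2
t012	target	2
t013	target	2
t014	target	2
t015	target	2
t016	target	2
t017	target	2
t018	target	2
t019	target	2
t020	target	2
t021	target	3
t022	target	3
t023	target	3
t024	target	3
t025	target	3
t026	target	3
t027	target	3
t028	target	3
t029	target	3
t030	target	3
t031	target	4
t032	target	4
t033	target	4
t034	target	4
t035	target	4
t036	target	4
t037	target	4
t038	target	4
t039	target	4
t040	target	4
d001	drug	1
d002	drug	1
d003	drug	1
d004	drug	1
d005	drug	1
d006	drug	1
d007	drug	1
d008	drug	1
d009	drug	1
d010	drug	1
d011	drug	1
d012	drug	1
d013	drug	1
d014	drug	2
d015	drug	2
d016	drug	2
d017	drug	2
d018	drug	2
d019	drug	2
d020	drug	2
d021	drug	2
d022	drug	2
d023	drug	2
d024	drug	2
d025	drug	2
d026	drug	2
d027	drug	3
d028	drug	3
d029	drug	3
d030	drug	3
d031	drug	3
d032	drug	3
d033	drug	3
d034	drug	3
d035	drug	3
d036	drug	3
d037	drug	3
d038	drug	3
d039	drug	4
d040	drug	4
d041	drug	4
d042	drug	4
d043	drug	4
d044	drug	4
d045	drug	4
d046	drug	4
d047	drug	4
d048	drug	4
d049	drug	4
d050	drug	4
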