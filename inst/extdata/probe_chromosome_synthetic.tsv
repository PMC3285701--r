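probe_id	chromosome
cg00000001	chrX
cg00000002	chrX
cg00000003	chrX
cg00000004	chrY
cg00000005	chrY
cg00000006	chr1
cg00000007	chr2
cg00000008	chr3
cg00000009	chr4
cg00000010	chr5
cg00000011	chr6
cg00000012	chr7
cg00000013	chr8
cg00000014	chr9
cg00000015	chr10
cg00000016	chr11
cg00000017	chr12
cg00000018	chr13
cg00000019	chr14
cg00000020	chr15
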