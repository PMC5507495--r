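sample	stage	treatment	replicate	total_reads	mapped_reads	reported_pct
st7.1_F_r1	7.1	fresh	1	25673031	24112015	93.9
st7.2_F_r1	7.2	fresh	1	38088839	34971702	91.8
st7.2_F_r2	7.2	fresh	2	34381008	31799644	92.5
st7.2_D_r1	7.2	dried	1	14259082	12881662	90.3
st7.2_D_r2	7.2	dried	2	66764127	60626937	90.8
st7.3_F_r1	7.3	fresh	1	22267371	20475504	92.0
st8.1_F_r1	8.1	fresh	1	14533337	13392050	92.2
st8.2_F_r1	8.2	fresh	1	22057408	19621133	89.0
st9_F_r1	9	fresh	1	28824583	26457357	91.8
st9_F_r2	9	fresh	2	23064604	21097336	91.5
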