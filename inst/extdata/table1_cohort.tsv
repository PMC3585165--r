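case_id	group	site_of_onset	gender	age	duration_months	alsfrs_r	biopsied_muscle
1	control		Male	59			deltoid
2	control		Female	62			deltoid
3	control		Male	66			deltoid
4	control		Female	60			deltoid
5	control		Female	64			deltoid
6	control		Female	70			deltoid
7	control		Male	65			deltoid
8	ALS	Spinal	Male	73		34	quadriceps
9	ALS	Spinal	Female	72	11	33	quadriceps
10	ALS	Spinal	Female	59	13	35	deltoid
11	ALS	Bulbar	Male	54	8	38	deltoid
12	ALS	Spinal	Male	72	18	35	deltoid
13	ALS	Spinal	Female	55	9	32	deltoid
14	ALS	Bulbar	Male	64		36	quadriceps
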