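sample_id	breed	sex	neutered	age_years	condition
S01	A	M	TRUE	14	healthy
S02	A	F	TRUE	7.7	healthy
S03	A	M	TRUE	12.4	healthy
S04	A	F	TRUE	13.7	healthy
S05	B	M	TRUE	4.9	healthy
S06	B	F	TRUE	7.2	healthy
S07	B	M	TRUE	9.1	healthy
S08	B	F	TRUE	5.3	healthy
S09	C	M	TRUE	9	healthy
S10	C	F	TRUE	11	healthy
S11	C	M	TRUE	9.7	healthy
S12	C	F	TRUE	7.8	healthy
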