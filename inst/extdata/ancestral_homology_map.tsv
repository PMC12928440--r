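ancestral_chromosome	O_sativa	S_bicolor	E_tef	O_thomaeum	Z_japonica	S_alterniflorus	S_maritimus_copy1	S_maritimus_copy2	S_maritimus_copy3	S_maritimus_copy4
A1	1	3	3A, 3B	3	5, 6	2, 5, 3, 8	3	16, 21	9	15, 45, 50
A2	2	4, 1	1A, 1B	1	7, 8	9, 13, 6, 15	1	2	7	12, 26
A3	3	1	4A, 4B	4	1, 2	4, 7, 1, 12	4, 56	60, 43, 18	20, 22	64, 14, 19
A4	4	6	7A, 7B	6	11, 12	23, 26, 25, 30	51, 44, 37	47, 57, 59, 46	53, 29	52, 24
A5	5	9	9A, 9B	5	17, 18	1, 12, 18, 22	4	43, 40, 49	10	23, 39
A6	6	2, 10	2A, 2B	2	19, 20	14, 21, 10, 11	8	36, 25	5	41, 30, 62, 38, 54
A7	7	2	5A, 5B	7	3, 4	19, 27, 24, 28	48, 17, 63	27, 55, 42	32, 35	34, 28
A8	8	7	8A, 8B	9	13, 14	16, 17, 20, 29	6	11, 61	13	66, 33, 31
A9	9	2, 10	2A, 2B	2	19, 20	14, 21, 10, 11	8	36, 25	5	41, 30, 62, 38, 54
A10	10	4, 1	1A, 1B	1	7, 8	9, 13, 6, 15, 4	1	2	7	12, 26
A11	11	5	6A, 6B	8	9, 10	16, 17, 7, 31	6	11	20, 22	14, 19
A12	12	8	10A, 10B	10	15, 16	19, 27, 6, 4	48, 17	27, 55, 42	7	12, 26
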