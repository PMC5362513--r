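table	sample_id	sample_type	locus_id	polymerase	preamplified	cycles	n_mut_pos	n_wt_pos	percent_mutant_printed
t4	JHU Pt 1	patient	F877L	Phusion	TRUE	22	5	18298	0.027
t4	JHU Pt 2	patient	F877L	Phusion	TRUE	22	8	31108	0.026
t4	JHU Pt 3	patient	F877L	Phusion	TRUE	22	5	27672	0.018
t4	JHU Pt 4	patient	F877L	Phusion	TRUE	22	5	35181	0.014
t4	JHU Pt 5	patient	F877L	Phusion	TRUE	22	11	32975	0.033
t4	JHU Pt 6	patient	F877L	Phusion	TRUE	22	0	41833	0.000
t4	JHU Pt 7	patient	F877L	Phusion	TRUE	22	7	68073	0.010
t4	JHU Pt 8	patient	F877L	Phusion	TRUE	22	10	36587	0.027
t4	JHU Pt 9	patient	F877L	Phusion	TRUE	22	6	25642	0.023
t4	JHU Pt 10	patient	F877L	Phusion	TRUE	22	4	59673	0.007
t4	JHU Pt 11	patient	F877L	Phusion	TRUE	22	8	37478	0.021
t4	WT Genomic DNA	wt_control	F877L	Phusion	TRUE	22	11	30348	0.036
t4	No Template Control	ntc	F877L	Phusion	TRUE	22	0	0	0.000
t4	WT Genomic DNA	wt_control	F877L	Phusion	FALSE	NA	0	36018	0.000
t4	F877L Mutant Control	mutant_control	F877L	Phusion	FALSE	NA	964	0	100
t4	No Template Control	ntc	F877L	Phusion	FALSE	NA	0	0	0.000
t4	JHU Pt 3	patient	F877L	SuperFi	TRUE	22	0	14824	0.000
t4	JHU Pt 4	patient	F877L	SuperFi	TRUE	22	0	14164	0.000
t4	JHU Pt 7	patient	F877L	SuperFi	TRUE	22	0	40588	0.000
t4	JHU Pt 8	patient	F877L	SuperFi	TRUE	22	0	10163	0.000
t4	JHU Pt 10	patient	F877L	SuperFi	TRUE	22	0	16317	0.000
t4	JHU Pt 11	patient	F877L	SuperFi	TRUE	22	0	17926	0.000
t4	WT Genomic DNA	wt_control	F877L	SuperFi	TRUE	22	0	44104	0.000
t4	No Template Control	ntc	F877L	SuperFi	TRUE	22	0	0	0.000
t4	WT Genomic DNA	wt_control	F877L	SuperFi	FALSE	NA	0	7761	0.000
t4	F877L Mutant Control	mutant_control	F877L	SuperFi	FALSE	NA	810	0	100
t4	No Template Control	ntc	F877L	SuperFi	FALSE	NA	0	0	0.000
t5	JHU Pt 1	patient	T878A	Phusion	TRUE	22	1	11707	0.009
t5	JHU Pt 3	patient	T878A	Phusion	TRUE	22	1	15126	0.007
t5	JHU Pt 4	patient	T878A	Phusion	TRUE	22	3	26983	0.011
t5	JHU Pt 7	patient	T878A	Phusion	TRUE	22	0	12156	0.000
t5	JHU Pt 8	patient	T878A	Phusion	TRUE	22	1	24205	0.004
t5	JHU Pt 10	patient	T878A	Phusion	TRUE	22	0	51299	0.000
t5	JHU Pt 11	patient	T878A	Phusion	TRUE	22	1	27082	0.004
t5	WT Genomic DNA	wt_control	T878A	Phusion	TRUE	22	2	36329	0.006
t5	No Template Control	ntc	T878A	Phusion	TRUE	22	0	0	0.000
t5	WT Genomic DNA	wt_control	T878A	Phusion	FALSE	NA	0	16132	0.000
t5	T878A Mutant Control	mutant_control	T878A	Phusion	FALSE	NA	122	0	100
t5	No Template Control	ntc	T878A	Phusion	FALSE	NA	0	0	0.000
t5	JHU Pt 1	patient	T878A	SuperFi	TRUE	22	0	41931	0.000
t5	JHU Pt 3	patient	T878A	SuperFi	TRUE	22	0	26745	0.000
t5	JHU Pt 4	patient	T878A	SuperFi	TRUE	22	0	30737	0.000
t5	JHU Pt 7	patient	T878A	SuperFi	TRUE	22	0	35931	0.000
t5	JHU Pt 8	patient	T878A	SuperFi	TRUE	22	0	27729	0.000
t5	JHU Pt 10	patient	T878A	SuperFi	TRUE	22	0	20279	0.000
t5	JHU Pt 11	patient	T878A	SuperFi	TRUE	22	0	32648	0.000
t5	WT Genomic DNA	wt_control	T878A	SuperFi	TRUE	22	0	21511	0.000
t5	No Template Control	ntc	T878A	SuperFi	TRUE	22	0	0	0.000
t5	T878A-positive cfDNA	positive_cfdna	T878A	SuperFi	TRUE	22	233	11890	1.960
t5	WT Genomic DNA	wt_control	T878A	SuperFi	FALSE	NA	0	24915	0.000
t5	T878A Mutant Control	mutant_control	T878A	SuperFi	FALSE	NA	7502	0	100
t5	No Template Control	ntc	T878A	SuperFi	FALSE	NA	0	0	0.000
t6	WT Genomic DNA	wt_control	F877L	Phusion	TRUE	22	11	30348	0.036
t6	WT Genomic DNA	wt_control	F877L	Phusion	TRUE	12	1	8539	0.012
t6	WT Genomic DNA	wt_control	F877L	SuperFi	TRUE	22	0	44104	0.000
t6	WT Genomic DNA	wt_control	T878A	Phusion	TRUE	22	2	36329	0.006
t6	WT Genomic DNA	wt_control	T878A	Phusion	TRUE	12	1	9617	0.010
t6	WT Genomic DNA	wt_control	T878A	SuperFi	TRUE	22	0	21511	0.000
t7	JHU Pt 3	patient	W742C	Phusion	TRUE	22	4	25067	0.016
t7	JHU Pt 7	patient	W742C	Phusion	TRUE	22	0	19753	0.000
t7	WT Genomic DNA	wt_control	W742C	Phusion	TRUE	22	0	17573	0.000
t7	No Template Control	ntc	W742C	Phusion	TRUE	22	0	0	0.000
t7	WT Genomic DNA	wt_control	W742C	Phusion	FALSE	NA	0	31225	0.000
t7	W742C Mutant Control	mutant_control	W742C	Phusion	FALSE	NA	10602	0	100
t7	No Template Control	ntc	W742C	Phusion	FALSE	NA	0	0	0.000
t7	JHU Pt 3	patient	W742C	SuperFi	TRUE	22	38	33611	0.113
t7	JHU Pt 7	patient	W742C	SuperFi	TRUE	22	0	15958	0.000
t7	WT Genomic DNA	wt_control	W742C	SuperFi	TRUE	22	0	37069	0.000
t7	No Template Control	ntc	W742C	SuperFi	TRUE	22	0	0	0.000
t7	WT Genomic DNA	wt_control	W742C	SuperFi	FALSE	NA	0	31225	0.000
t7	W742C Mutant Control	mutant_control	W742C	SuperFi	FALSE	NA	10602	0	100
t7	No Template Control	ntc	W742C	SuperFi	FALSE	NA	0	0	0.000
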