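method	bpd_ppv	bpd_rank	mdd_ppv	mdd_rank	scz_ppv	scz_rank	mpv_ppv	mpv_rank	wbc_ppv	wbc_rank	median_rank
MTAG	0.571	1	1.000	1	1.000	2	NA	18	1.000	1	1
TWAS/FUSION	0.500	3	NA	18	0.500	6	0.533	4	0.368	8	6
UTMOST	0.333	5	0.000	9	0.500	6	0.440	8	0.300	11	8
Jepeg	0.333	5	NA	18	1.000	2	0.333	11	0.375	7	7
COLOC	0.200	8	0.000	9	0.600	4	0.607	3	0.566	3	4
EUGENE	0.500	3	NA	18	0.400	8	0.329	12	0.282	12	12
Sherlock	0.182	11	0.000	9	0.286	9	0.690	1	0.538	4	9
moloc	0.000	14	0.000	9	0.667	3	0.455	5	0.500	5	5
GPA	0.231	7	0.000	9	0.275	10	0.451	6	0.335	10	9
Suggestive	0.286	6	0.000	9	0.455	7	0.338	10	0.349	9	9
fgwas	0.143	10	0.077	2	0.190	13	0.442	7	0.250	14	10
GenoSkyline	0.083	12	NA	18	0.273	11	0.285	13	0.250	14	13
GenoCanyon	0.079	13	0.000	9	0.196	12	0.222	14	0.207	16	13
LSMM	0.185	9	NA	18	0.181	14	0.216	15	0.225	15	15
SMR	NA	18	NA	18	0.000	15	0.429	9	0.400	6	15
Weighted eQTL	NA	18	NA	18	NA	18	0.667	2	0.667	2	18
fastENLOC	NA	18	NA	18	NA	18	NA	18	NA	18	18
Sveinbjornsson	NA	18	NA	18	NA	18	NA	18	NA	18	18
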