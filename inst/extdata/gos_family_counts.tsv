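# source: published pooled GOS survey read counts and 835-genome copy statistics for the detoxification family set
# note: TehB read counts as printed are arithmetically inconsistent and are stored as NA
family	display_name	category	gos_initial	gos_reciprocal	genome_mean	genome_cv
ArsC	Arsenate reductase	metal_resistance	993	853	1.1	108
CutA	Divalent ion tolerance protein	metal_resistance	1511	1511	0.4	127
CopC	Copper resistance protein CopC	metal_resistance	472	426	0.3	206
Cu-oxidase_3	Multicopper oxidase	metal_resistance	435	313	0.7	154
CutC	Copper transporter	metal_resistance	258	258	0.2	182
TehB	Tellurite resistance protein	metal_resistance	NA	NA	0.2	206
ArsB	Arsenical pump membrane protein	metal_resistance	177	19	0.3	218
YodA	Cadmium binding protein	metal_resistance	1	0	0.0	492
MFS_1	Major facilitator family	transporters	22627	19301	23.1	108
ACR_tran	ACR transporter	transporters	10591	10337	4.4	126
MatE	Multi antimicrobial extrusion protein	transporters	5164	4308	2.2	120
HlyD	Efflux pump	transporters	4048	2693	6.9	121
Multi_Drug_Res	Small Multidrug Resistance protein	transporters	2194	2097	1.0	134
C4dic_mal_tran	C4-dicarboxylate transporter	transporters	71	71	0.3	173
AhpC-TSA	Peroxiredoxin	oxidative_stress	14009	7397	3.5	91
Thioredoxin	Thioredoxin	oxidative_stress	8221	4668	2.7	67
Redoxin	Redoxin	oxidative_stress	13178	4410	1.7	108
peroxidase	Peroxidase	oxidative_stress	3067	3065	0.4	154
GSHPx	Glutathione peroxidase	oxidative_stress	2380	2218	0.6	131
Sod_Fe_C	Superoxide dismutase	oxidative_stress	935	796	0.9	78
Catalase	Catalase	oxidative_stress	91	88	0.8	146
BacA	Bacitracin resistance protein	other_detox	2803	2799	0.8	73
OstA_C	Organic solvent tolerance protein	other_detox	1094	1086	0.4	121
FUSC	Fusaric acid resistance protein	other_detox	67	65	0.8	205
CCP_MauG	Di-haem cytochrome c peroxidase	other_detox	606	582	0.5	211
Beta-lactamase	Beta-lactamase	other_detox	5196	4985	2.6	149
Oxidored_FMN	NADH oxidase	other_detox	2598	2349	1.9	130
Transpeptidase	Penicillin binding transpeptidase	other_detox	9702	8379	2.1	72
MarR	Multiple antibiotic resistance operon repressor	other_detox	2949	2078	5.8	128
TetR_C_2	MAATS-type multidrug transcriptional repressor	other_detox	21	12	0.1	343
FMN_red	NADPH-dependent FMN reductase	other_detox	2222	1076	2.5	110
EF_TS	Elongation factor TS	control	2780	2734	0.8	49
DNA_pol_A	DNA polymerase A	control	5372	4973	0.9	55
RNA_pol_Rpb2_6	RNA polymerase rpoB	control	5847	5106	1.0	9
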