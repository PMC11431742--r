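gene	tcdd_level	ccrcc_level	os_fdr_p	low_surv_level	x_mark
AHR	HIGH	LOW	5.47e-4	LOW	X
ANAPC16	LOW	HIGH	2.89e-4	LOW	
AR	HIGH	LOW	6.24e-11	LOW	X
ARNT2	HIGH	HIGH	2.60e-2	LOW	
BRCA1	HIGH	LOW	7.22e-2	LOW	
CCDC43	HIGH	LOW	9.01e-5	LOW	X
CHMP1A	LOW	LOW	7.22e-2	HIGH	
CLEC11A	HIGH	HIGH	5.20e-3	HIGH	X
CYP1B1	LOW	LOW	1.13e-3	HIGH	
DDB1	LOW	HIGH	6.76e-7	LOW	
DNAJA2	LOW	LOW	1.95e-10	LOW	X
EGLN3	HIGH	LOW	1.38e-2	LOW	X
EP300	HIGH	LOW	2.13e-5	LOW	X
EPHX2	LOW	HIGH	2.13e-5	LOW	
EPHX4	HIGH	LOW	9.98e-2	HIGH	
FASN	LOW	LOW	1.10e-5	HIGH	
GSTA4	LOW	HIGH	3.12e-3	LOW	
GSTM2	HIGH	HIGH	4.70e-3	HIGH	X
GSTM3	LOW	HIGH	1.13e-3	LOW	
GSTM4	LOW	HIGH	1.51e-1	LOW	
GSTM5	HIGH	HIGH	1.71e-1	LOW	
HSP90AB1	LOW	LOW	2.24e-4	LOW	X
HSPB8	HIGH	LOW	7.81e-2	LOW	
IVNS1ABP	HIGH	HIGH	9.78e-7	LOW	
KIF14	HIGH	LOW	1.82e-6	HIGH	
MAF	LOW	LOW	7.43e-4	LOW	X
MGST1	LOW	HIGH	3.39e-2	HIGH	X
MGST2	LOW	HIGH	2.45e-6	LOW	
MPHOSPH8	LOW	LOW	2.50e-3	LOW	X
NCOA1	HIGH	HIGH	2.69e-3	LOW	
NCOA7	LOW	HIGH	9.78e-7	LOW	
NR2F1	LOW	HIGH	2.69e-3	LOW	
PARP1	LOW	LOW	5.02e-2	HIGH	
PPP1R12A	LOW	LOW	3.24e-2	LOW	X
PSMC2	LOW	LOW	1.09e-1	HIGH	
PSMD3	LOW	LOW	4.00e-5	HIGH	
PTGES3	HIGH	LOW	2.89e-4	LOW	X
PUS7	LOW	LOW	8.77e-2	HIGH	
RAF1	HIGH	LOW	1.30e-1	HIGH	
RB1	HIGH	LOW	2.60e-6	LOW	X
RBX1	LOW	LOW	2.50e-3	HIGH	
RELA	LOW	LOW	9.98e-2	HIGH	
SF3B3	LOW	LOW	7.43e-4	LOW	X
SMAD4	LOW	HIGH	2.64e-5	LOW	
SUMO2	HIGH	LOW	1.57e-2	HIGH	
SUV39H1	LOW	LOW	2.50e-3	LOW	X
TERF2IP	LOW	HIGH	1.71e-1	HIGH	X
TOMM34	LOW	HIGH	7.06e-5	HIGH	X
TRIM52	HIGH	LOW	9.77e-3	HIGH	
UBLCP1	LOW	LOW	2.08e-2	LOW	X
UGT1A1	HIGH	HIGH	1.71e-1	HIGH	
VIM	HIGH	LOW	2.50e-3	HIGH	
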