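gene	cluster
HSP90AB1	Cytosolic complex
PTGES3	Cytosolic complex
DNAJA2	Cytosolic complex
HSPB8	Cytosolic complex
TOMM34	Cytosolic complex
AHR	Transcription partners
AR	Transcription partners
ARNT2	Transcription partners
EP300	Transcription partners
NCOA1	Transcription partners
RELA	Transcription partners
SMAD4	Transcription partners
MAF	Transcription partners
NR2F1	Transcription partners
BRCA1	Transcription partners
CYP1B1	TCDD transcript
GSTA4	TCDD transcript
GSTM2	TCDD transcript
GSTM3	TCDD transcript
GSTM4	TCDD transcript
GSTM5	TCDD transcript
MGST1	TCDD transcript
MGST2	TCDD transcript
EPHX2	TCDD transcript
EPHX4	TCDD transcript
UGT1A1	TCDD transcript
FASN	TCDD transcript
RB1	Regulatory functions
RAF1	Regulatory functions
EGLN3	Regulatory functions
VIM	Regulatory functions
KIF14	Regulatory functions
SUV39H1	Regulatory functions
MPHOSPH8	Regulatory functions
SUMO2	Degradation (no TCDD)
DDB1	Degradation (no TCDD)
RBX1	Degradation (no TCDD)
PSMC2	Degradation (no TCDD)
PSMD3	Degradation (no TCDD)
UBLCP1	Degradation (no TCDD)
ANAPC16	Degradation (no TCDD)
CHMP1A	Degradation (no TCDD)
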