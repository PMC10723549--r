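MOTILITY_ACTIN	synthetic mini set: cell motility / cytoskeleton	TMSB10	AIF1	CAPG	RHOA	TYROBP	ACTB	S100A11
IMMUNE_EVASION	synthetic mini set: immune evasion	CD74	B2M	TNFAIP3	PTPRC
METABOLISM_REDOX	synthetic mini set: metabolism	GPX1	SEPP1	UQCRB
MELANOCYTE_PROGRAM	synthetic mini set: melanocytic lineage	MITF	MLANA	DCT	TYR	GP100	HTR2B	PRAME
MACROPHAGE_PROGRAM	synthetic mini set: macrophage lineage	PTPRC	CD14	CD163	CD68	AIF1	TYROBP
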