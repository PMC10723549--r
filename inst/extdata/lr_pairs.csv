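ligand,receptor,annotation
GAS6,AXL,tumor-hybrid axis; actin remodeling
CXCL12,CXCR4,hybrid-T cell axis; chemotaxis
LGALS9,P4HB,hybrid-tumor axis; EMT
IGF1,IGF1R,hybrid-tumor axis; liver-tropic growth signaling
TYROBP,CD44,hybrid-tumor axis; conserved across samples
APP,CD74,macrophage/tumor-hybrid axis
ANXA1,FPR1,hybrid-macrophage axis; invasiveness
ANXA1,FPR3,hybrid-macrophage axis; invasiveness
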