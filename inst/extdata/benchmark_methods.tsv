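method	force_field	solvation	solvent_class	temperature
MM3_HCT	MM3-2000	HCT	implicit	300
MM3_TIP3P	MM3-2000	TIP3P	explicit	300
MMFF94_HCT_1000K	MMFF94	HCT	implicit	1000
OPLSaa_HCT	OPLS-aa	HCT	implicit	300
GLYCAM06_GB	GLYCAM-06	GB	implicit	300
GLYCAM06_TIP3P	GLYCAM-06	TIP3P	explicit	300
CHARMM36_GB	CHARMM36	GB	implicit	300
CHARMM36_TIP3P	CHARMM36	TIP3P	explicit	300
AmberFF14SB_GB	Amber-ff14SB	GB	implicit	300
AmberFF14SB_TIP3P	Amber-ff14SB	TIP3P	explicit	300
DFT_SMD	PBE0-D3/def2-TZVP	SMD	dft	300
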