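molecule	description	MM3_HCT	MM3_TIP3P	MMFF94_HCT_1000K	OPLSaa_HCT	GLYCAM06_GB	GLYCAM06_TIP3P	CHARMM36_GB	CHARMM36_TIP3P	AmberFF14SB_GB	AmberFF14SB_TIP3P	DFT_SMD
1	aDGlcp-(1-2)-bDFruf	0.17	0.22	0.23	0.23	0.18	0.20	0.15	0.28	0.17	0.15	0.18
2	aDManp-(1-3)-aDManp-OMe	0.09	0.13	0.30	0.30	0.05	0.03	0.24	0.37	0.11	0.18	0.05
3	aDManp-(1-6)-aDManp-OMe	0.14	0.14	0.22	0.22	0.17	0.18	0.15	0.03	0.15	0.15	0.17
4	aDManp-(1-6)-bDManp-OMe	0.03	0.02	0.10	0.10	0.06	0.07	0.04	0.51	0.04	0.06	0.07
5	bDGlcpNAc-(1-6)-aDManp-OMe	0.04	0.05	0.05	0.05	0.05	0.05	0.12	0.23	0.05	0.04	0.03
6	bDGlcpNAc-(1-2)-aDManp-OMe	0.09	0.08	0.07	0.07	0.13	0.13	0.08	0.20	0.13	0.15	0.08
7	aDRhap4N-(1-2)-aDRhap4N-OMe	0.10	0.07	0.29	0.29	0.28	0.15	0.41	0.13	0.09	0.15	0.04
8	aDRhap4N-(1-3)-aDRhap4N-OMe	0.16	0.10	0.32	0.32	0.16	0.13	0.17	0.26	0.18	0.18	0.07
9	aDGalpA-(1-3)-aDFucpNAc4N-OMe	0.16	0.16	0.18	0.18	0.29	0.20	0.31	0.31	0.32	0.17	0.18
10	aLRhap-(1-2)-aLRhap-OMe	0.10	0.10	0.16	0.16	0.14	0.14	0.21	0.38	0.16	0.14	0.13
11	aKDO-(2-4)-aKDO-OAllyl	0.15	0.16	0.25	0.25	0.20	0.08	0.25	0.18	0.20	0.12	0.10
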