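genome_id	completeness	contamination	abundance
AOB1	96.1	0.8	6
AOB2	88.4	1.4	4
AOB3	79.2	2.1	3
AMX1	92.7	1.1	6
AMX2	98.2	0.3	12
AMX3	85.3	1.9	4
PRO1	78.5	2.4	0.4
PRO2	90.3	0.9	3
PRO3	95.8	0.5	0.8
PRO4	83.1	1.6	0.3
PRO5	87.6	2.2	0.6
PRO6	74.9	3.1	2
PRO7	72.3	2.8	0.2
PRO8	81.7	1.2	0.3
PRO10	70.4	3.4	0.2
PRO11	86.2	0.7	0.5
PRO12	77.8	2.6	0.3
CFX1	84.5	1.8	1.2
CFX2	93.6	0.6	8.75
CFX3	76.1	2.9	1
CFX4	82.9	1.3	0.9
CFX5	71.8	3.7	0.7
CFX6	88.9	0.4	1.1
CFX7	79.7	2.3	0.8
CFX8	91.4	1	1.3
CFX9	75.2	3.2	0.6
CFX10	73.6	2.7	0.5
CFX11	85.8	1.5	1
CFX12	80.6	2	0.9
CFX13	78.1	3	0.8
CFX14	72.9	3.6	0.7
CFX15	89.5	0.8	0.34
CLB1	94.2	0.5	5.2
CLB2	83.8	1.7	0.4
CLB3	76.7	2.5	0.3
CLB4	70.9	3.3	0.2
ARM1	87.1	1.2	4
ACD2	82.4	1.9	0.5
ACT2	74.3	2.8	0.23
IGN1	86.9	0.9	0.6
IGN2	81.2	1.6	0.4
BCG1	77.4	2.2	0.5
BCT2	84.1	1.4	0.4
BCT5	73.2	3.1	0.3
BCT6	79.9	2	0.3
BCT11	75.6	2.6	0.2
BCD1	71.3	3.5	2
BCD2	88.2	1.1	2
PAT1	62.4	0	0.2
PAT3	70.2	3.8	0.2
PLA1	80.1	1.8	0.3
VER1	76.3	2.4	0.3
VER2	68.5	0	0.2
VER3	65.7	0	0.2
GMM2	91.8	0.7	0.4
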