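genome_id	gene	label
AOB1	amoA	
AOB1	amoB	
AOB1	amoC	
AOB1	amoD	
AOB1	amoE	
AOB1	hao	
AOB1	nirK	
AOB1	norB	
AOB1	norC	
AOB1	copC	
AOB1	copD	
AOB2	amoA	
AOB2	amoB	
AOB2	amoC	
AOB2	amoD	
AOB2	amoE	
AOB2	hao	
AOB2	nirK	
AOB2	norB	
AOB2	norC	
AOB2	copC	
AOB2	copD	
AOB3	amoA	
AOB3	amoB	
AOB3	amoC	
AOB3	amoD	
AOB3	amoE	
AOB3	hao	
AOB3	nirK	
AOB3	norB	
AOB3	norC	
AOB3	copC	
AOB3	copD	
AMX1	hzsA	
AMX1	hzsB	
AMX1	hzsC	
AMX1	hdh	
AMX1	nxrA	anammox
AMX1	nxrB	anammox
AMX1	nirK	
AMX1	hao_like.01	nh2oh_to_no
AMX1	hao_like.02	nh2oh_to_no
AMX1	hao_like.03	nh2oh_to_no
AMX1	hao_like.04	no2_to_no_or_nh2oh
AMX1	hao_like.05	no2_to_no_or_nh2oh
AMX1	hao_like.06	no2_to_no_or_nh2oh
AMX1	hao_like.07	
AMX1	hao_like.08	
AMX1	hao_like.09	
AMX1	hao_like.10	
AMX2	hzsA	
AMX2	hzsB	
AMX2	hzsC	
AMX2	hdh	
AMX2	nxrA	anammox
AMX2	nxrB	anammox
AMX2	hao_like.01	nh2oh_to_no
AMX2	hao_like.02	nh2oh_to_no
AMX2	hao_like.03	nh2oh_to_no
AMX2	hao_like.04	no2_to_no_or_nh2oh
AMX2	hao_like.05	no2_to_no_or_nh2oh
AMX2	hao_like.06	no2_to_no_or_nh2oh
AMX2	hao_like.07	
AMX2	hao_like.08	
AMX2	hao_like.09	
AMX2	hao_like.10	
AMX3	hzsA	
AMX3	hzsB	
AMX3	hzsC	
AMX3	hdh	
AMX3	nxrA	anammox
AMX3	nxrB	anammox
AMX3	hao_like.01	nh2oh_to_no
AMX3	hao_like.02	no2_to_no_or_nh2oh
AMX3	hao_like.03	no2_to_no_or_nh2oh
AMX3	hao_like.04	no2_to_no_or_nh2oh
AMX3	hao_like.05	
AMX3	hao_like.06	
PRO1	nirS	
PRO1	nosZ	cladeII
PRO2	narG	
PRO2	narH	
PRO2	narI	
PRO2	nirS	
PRO2	norB	
PRO2	norC	
PRO3	narG	
PRO3	narH	
PRO3	narI	
PRO3	nirS	
PRO3	norB	
PRO3	norC	
PRO3	nosZ	cladeI
PRO3	nxrA	periplasmic
PRO3	nxrB	periplasmic
PRO3	hao_like.01	
PRO3	hao_like.02	
PRO4	nirK	
PRO5	narG	
PRO5	narH	
PRO5	narI	
PRO5	nirK	
PRO5	nosZ	cladeII
PRO5	hao_like.01	
PRO6	narG	
PRO6	narH	
PRO6	narI	
PRO6	nxrA	periplasmic
PRO6	nxrB	periplasmic
PRO7	nrfA	
PRO7	nrfH	
PRO7	nirK	
PRO8	nrfA	
PRO8	nrfH	
PRO8	nirK	
PRO10	nirK	
PRO11	narG	
PRO11	narH	
PRO11	narI	
PRO11	nxrA	periplasmic
PRO11	nxrB	periplasmic
PRO11	hao_like.01	
PRO12	narG	
PRO12	narH	
PRO12	narI	
PRO12	nxrA	periplasmic
PRO12	nxrB	periplasmic
CFX1	nxrA	periplasmic
CFX1	nxrB	periplasmic
CFX2	narG	
CFX2	narH	
CFX2	nirK	
CFX3	narG	
CFX3	narH	
CFX3	narI	
CFX3	nirS	
CFX3	norZ	
CFX4	narG	
CFX4	narH	
CFX4	narI	
CFX4	nirK	
CFX4	norZ	
CFX5	norZ	
CFX6	nirS	
CFX6	nosZ	cladeII
CFX7	nirK	
CFX8	narG	
CFX8	narH	
CFX8	narI	
CFX8	nrfA	
CFX8	nrfH	
CFX8	nosZ	cladeII
CFX9	narG	
CFX9	narH	
CFX9	narI	
CFX9	nirK	
CFX9	nosZ	cladeII
CFX9	nxrA	periplasmic
CFX9	nxrB	periplasmic
CFX10	nrfA	
CFX10	nrfH	
CFX10	nosZ	cladeII
CFX11	narG	
CFX11	narH	
CFX11	narI	
CFX11	nrfA	
CFX11	nrfH	
CFX12	nrfA	
CFX12	nrfH	
CFX12	nosZ	cladeII
CFX13	nrfA	
CFX13	nrfH	
CFX13	nosZ	cladeII
CFX14	nrfA	
CFX14	nrfH	
CFX14	nosZ	cladeII
CFX15	narG	
CFX15	narH	
CLB1	narG	
CLB1	narH	
CLB1	nosZ	cladeII
CLB2	narG	
CLB2	narH	
CLB2	narI	
CLB2	nirB	
CLB2	nirD	
CLB3	narG	
CLB3	narH	
CLB3	narI	
CLB3	nirB	
CLB3	nirD	
CLB4	nrfA	
CLB4	nrfH	
CLB4	nosZ	cladeII
ARM1	nxrA	periplasmic
ARM1	nxrB	periplasmic
ACD2	narG	
ACD2	narH	
ACD2	narI	
ACD2	napA	
ACD2	napB	
ACD2	nrfA	
ACD2	nrfH	
ACT2	narG	
ACT2	narH	
IGN1	narG	
IGN1	narH	
IGN1	narI	
IGN1	nosZ	cladeII
IGN2	narG	
IGN2	narH	
IGN2	narI	
IGN2	nosZ	cladeII
BCG1	narG	
BCG1	narH	
BCG1	narI	
BCG1	nosZ	cladeII
BCT2	nirS	
BCT2	nosZ	cladeII
BCT5	nirK	
BCT5	nosZ	cladeII
BCT6	nirK	
BCT6	nosZ	cladeII
BCT11	narG	
BCT11	narH	
BCT11	narI	
BCT11	nosZ	cladeII
BCD1	nrfA	
BCD1	nrfH	
BCD1	nosZ	cladeII
BCD2	narG	
BCD2	narH	
BCD2	narI	
BCD2	nosZ	cladeII
PAT3	nirK	
PAT3	nrfA	
PAT3	nrfH	
PLA1	nirK	
VER1	nirS	
VER2	nirS	
VER3	nirK	
GMM2	nirK	
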