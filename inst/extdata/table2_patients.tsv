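case_id	age	gender	histology	subtype	tumor_type	partner	ntrk_gene	classification	fusion_type	tmb	msi	novelty
1	1	Female	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	ETV6	NTRK3	Definite	interchromosomal	0	MSS	Reported
2	1	Male	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	ETV6	NTRK3	Definite	interchromosomal	0	MSS	Reported
3	1	Female	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	ETV6	NTRK3	Definite	interchromosomal	6.9	MSS	Reported
4	1	Female	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	ETV6	NTRK3	Definite	interchromosomal	0.8	MSS	Reported
5	2	Female	Soft tissue sarcoma	Cellular plexiform schwannoma	Soft tissue sarcoma	TPM3	NTRK1	Definite	intrachromosomal	0	MSS	Reported
6	2	Male	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	ETV6	NTRK3	Definite	interchromosomal	3	MSS	Reported
7	3	Male	Soft tissue sarcoma	Rhabdomyosarcoma	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	1.2	MSS	Reported
8	4	Male	Soft tissue sarcoma	Infantile fibrosarcoma	Soft tissue sarcoma	TPM3	NTRK1	Definite	intrachromosomal	0.7	MSS	Reported
9	9	Male	Soft tissue sarcoma	Soft tissue sarcoma of the abdomen	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	1.2	MSS	Reported
10	15	Male	Soft tissue sarcoma	Soft tissue sarcoma of the abdomen	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	0.6	MSS	Reported
11	23	Male	Carcinoma	Mucoepidermoid carcinoma of trachea	Head and neck carcinoma	C7orf69	NTRK3	Likely	interchromosomal	0	MSS	Novel
12	29	Male	Soft tissue sarcoma	Spindle cell sarcoma of the prostate	Soft tissue sarcoma	RBPMS	NTRK3	Definite	interchromosomal	1.5	MSS	Reported
13	35	Male	Soft tissue sarcoma	Prostatic stromal tumor	Soft tissue sarcoma	IRF2BP2	NTRK1	Definite	intrachromosomal	4.7	Unknown	Reported
14	38	Female	Carcinoma	Thyroid tumor	Thyroid tumor	ETV6	NTRK3	Definite	interchromosomal	1.5	MSS	Reported
15	42	Female	Soft tissue sarcoma	Spindle cell sarcoma of the thigh	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	0.7	MSS	Reported
16	42	Male	Soft tissue sarcoma	Mucinous liposarcoma	Soft tissue sarcoma	MORF4L1	NTRK3	Definite	intrachromosomal	0.7	MSS	Novel
16	42	Male	Soft tissue sarcoma	Mucinous liposarcoma	Soft tissue sarcoma	PPFIA2	NTRK3	Definite	interchromosomal	0.7	MSS	Novel
17	43	Male	Soft tissue sarcoma	Spindle cell tumors of the sacrum	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	3	MSS	Reported
18	43	Female	Carcinoma	Non-small cell lung cancer	Non-small cell lung cancer	TPM3	NTRK1	Definite	intrachromosomal	0.8	MSS	Reported
19	43	Male	Carcinoma	Small cell lung cancer	Small cell lung cancer	ETV6	NTRK3	Definite	interchromosomal	16.4	MSS	Reported
20	43	Male	Carcinoma	Gastric cancer	Gastric cancer	INSRR	NTRK1	Likely	intrachromosomal	44.1	MSI-H	Novel
21	44	Male	Soft tissue sarcoma	High-grade spindle cell sarcoma of the small intestine	Soft tissue sarcoma	LMNA	NTRK1	Definite	intrachromosomal	2.5	MSS	Reported
22	46	Male	Carcinoma	Intrahepatic cholangiocarcinoma	Intrahepatic cholangiocarcinoma	PHF20	NTRK1	Likely	interchromosomal	42.5	MSI-H	Reported
23	48	Female	Carcinoma	Small cell lung cancer	Small cell lung cancer	ETV6	NTRK3	Definite	interchromosomal	14.8	MSS	Reported
24	48	Female	Carcinoma	Non-small cell lung cancer	Non-small cell lung cancer	RB1	NTRK3	Definite	interchromosomal	5.4	MSS	Novel
25	48	Male	Carcinoma	Hepatocellular carcinoma	Hepatocellular carcinoma	TTC28	NTRK3	Likely	interchromosomal	6.9	MSS	Novel
26	52	Male	Carcinoma	Non-small cell lung cancer	Non-small cell lung cancer	AMOTL2	NTRK1	Likely	interchromosomal	8.7	Unknown	Reported
27	53	Female	Carcinoma	Invasive breast cancer	Breast cancer	LINC01197	NTRK3	Likely	intrachromosomal	6.1	MSS	Novel
28	57	Male	Carcinoma	Colorectal cancer	Colorectal cancer	ETV6	NTRK3	Definite	interchromosomal	180.3	MSI-H	Reported
29	59	Male	Carcinoma	Colorectal cancer	Colorectal cancer	TPM3	NTRK1	Definite	intrachromosomal	8.5	MSS	Reported
30	59	Female	Carcinoma	Ovarian serous cystadenocarcinoma	Ovarian cancer	ITGA4	NTRK3	Definite	interchromosomal	3.9	MSS	Novel
31	61	Female	Carcinoma	Colorectal cancer	Colorectal cancer	TPM3	NTRK1	Definite	intrachromosomal	8.5	MSS	Reported
32	61	Male	Carcinoma	Non-small cell lung cancer	Non-small cell lung cancer	COL8A1	NTRK3	Definite	interchromosomal	10.8	MSS	Reported
33	63	Male	Carcinoma	Non-small cell lung cancer	Non-small cell lung cancer	PRDX1	NTRK1	Definite	intrachromosomal	1.5	MSS	Novel
34	64	Male	Carcinoma	Hepatocellular carcinoma	Hepatocellular carcinoma	PEAR1	NTRK1	Definite	intrachromosomal	6.9	MSS	Reported
35	66	Male	Carcinoma	Extrahepatic cholangiocarcinoma	Extrahepatic cholangiocarcinoma	MMP16	NTRK3	Likely	interchromosomal	6.1	MSS	Novel
36	67	Female	Soft tissue sarcoma	Uterine leiomyosarcoma	Soft tissue sarcoma	MEF2A	NTRK3	Definite	intrachromosomal	3.8	MSS	Novel
37	69	Female	Carcinoma	Colorectal cancer	Colorectal cancer	TPM3	NTRK1	Definite	intrachromosomal	78.1	MSI-H	Reported
38	71	Female	Carcinoma	Colorectal cancer	Colorectal cancer	TPR	NTRK1	Definite	intrachromosomal	54.9	MSI-H	Reported
39	72	Male	Carcinoma	Colorectal cancer	Colorectal cancer	ETV6	NTRK3	Definite	interchromosomal	56.2	MSI-H	Reported
40	76	Male	Carcinoma	Colorectal cancer	Colorectal cancer	LMNA	NTRK1	Definite	intrachromosomal	6.2	MSS	Reported
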