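variable	level	overall	positive
overall	All	10194	40
age_group	Infantile	12	4
age_group	Pediatric	157	6
age_group	Adult	10025	30
gender	Female	4039	15
gender	Male	6155	25
stage	I-II	3571	11
stage	III-IV	5652	23
stage	Unknown	971	6
msi	MSI-H	186	6
msi	MSS	9461	32
msi	Unknown	547	2
tumor_type	Soft tissue sarcoma	571	17
tumor_type	Colorectal cancer	1225	7
tumor_type	Non-small cell lung cancer	2039	5
tumor_type	Hepatocellular carcinoma	1133	2
tumor_type	Breast cancer	323	1
tumor_type	Small cell lung cancer	220	2
tumor_type	Extrahepatic cholangiocarcinoma	351	1
tumor_type	Head and neck carcinoma	175	1
tumor_type	Intrahepatic cholangiocarcinoma	555	1
tumor_type	Ovarian cancer	261	1
tumor_type	Gastric cancer	866	1
tumor_type	Thyroid tumor	32	1
tumor_type	Gallbladder carcinoma	240	0
tumor_type	Bone sarcoma	183	0
tumor_type	Cancer of unknown primary	120	0
tumor_type	Endocervical carcinoma	104	0
tumor_type	Endometrial carcinoma	61	0
tumor_type	Esophageal carcinoma	610	0
tumor_type	Gastrointestinal neuroendocrine tumor	74	0
tumor_type	Melanoma	59	0
tumor_type	Pancreatic cancer	498	0
tumor_type	Renal cell carcinoma	308	0
tumor_type	Small bowel carcinoma	57	0
tumor_type	Thymic tumor	33	0
tumor_type	Urothelial carcinoma	96	0
subtype	Fibrosarcoma	55	7
subtype	Infantile fibrosarcoma	12	6
subtype	Adult fibrosarcoma	43	1
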