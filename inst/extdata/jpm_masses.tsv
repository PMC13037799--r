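# Organ, tissue and content masses (kg): adult Japanese polygon-mesh male
# phantom (JPM), the voxel male phantom (JM-103) and the adult-Japanese-male
# average.  NA marks quantities with no published average.
organ	jpm	jm103	average
Adipose	17.386	14.192	13.900
Adrenal	0.014	0.015	0.014
Brain	1.470	1.529	1.470
Breast	0.022	0.023	0.022
Bronchi	0.011	0.009	NA
Colon	0.330	0.326	0.330
Colon content	0.360	0.360	0.360
Endosteum	0.466	0.574	NA
Esophagus	0.040	0.036	0.040
ET regions	0.004	0.043	NA
Eyeball	0.015	0.014	0.015
Gall bladder	0.008	0.008	0.008
Gall bladder content	0.050	0.049	0.050
Hard bone	5.351	6.730	4.500
Heart	0.380	0.389	0.380
Heart content	0.400	0.362	0.400
Kidney	0.320	0.333	0.320
Lens	0.0004	0.0004	0.0004
Liver	1.600	1.462	1.600
Lung	1.200	1.215	1.200
Lymphatic tissue	0.220	0.224	0.220
Marrow (active)	1.001	1.192	1.000
Marrow (inactive)	2.121	2.526	1.300
Muscle	27.429	28.198	27.500
Oral mucosa	0.00015	0.010	NA
Pancreas	0.130	0.136	0.130
Prostate	0.012	0.011	0.012
Salivary gland	0.082	0.086	0.082
Skin	2.411	2.189	2.400
Small intestine	0.590	0.557	0.590
Small intestine content	0.350	0.351	0.350
Spleen	0.140	0.139	0.140
Stomach	0.140	0.141	0.140
Stomach content	0.240	0.240	0.240
Tooth	0.059	0.061	0.045
Testis	0.037	0.036	0.037
Thymus	0.030	0.031	0.030
Thyroid	0.019	0.020	0.019
Tongue	0.067	0.062	0.067
Trachea	0.009	0.009	0.009
Urinary bladder	0.040	0.039	0.040
Urinary bladder content	0.100	0.102	0.100
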