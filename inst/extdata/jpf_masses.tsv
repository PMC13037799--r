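# Organ, tissue and content masses (kg): adult Japanese polygon-mesh female
# phantom (JPF), the voxel female phantom (JF-103) and the
# adult-Japanese-female average.  NA marks quantities with no published
# average.
organ	jpf	jf103	average
Adipose	15.048	13.815	15.200
Adrenal	0.013	0.012	0.013
Brain	1.320	1.335	1.320
Breast	0.300	0.309	0.300
Bronchi	0.012	0.020	NA
Colon	0.260	0.244	0.260
Colon content	0.280	0.289	0.280
Endosteum	0.352	0.406	NA
Esophagus	0.030	0.031	0.030
ET regions	0.002	0.030	NA
Eyeball	0.012	0.012	0.012
Gall bladder	0.006	0.006	0.006
Gall bladder content	0.038	0.035	0.038
Hard bone	4.027	4.460	3.400
Heart	0.300	0.325	0.300
Heart content	0.320	0.316	0.320
Kidney	0.280	0.271	0.280
Lens	0.0003	0.0003	0.0003
Liver	1.400	1.311	1.400
Lung	0.910	0.978	0.910
Lymphatic tissue	0.170	0.173	0.170
Marrow (active)	0.775	0.956	0.780
Marrow (inactive)	1.557	1.911	0.990
Muscle	20.704	20.212	20.790
Oral mucosa	0.0001	0.008	NA
Ovary	0.011	0.012	0.011
Pancreas	0.110	0.113	0.110
Salivary gland	0.062	0.063	0.062
Skin	1.807	1.898	1.800
Small intestine	0.450	0.467	0.450
Small intestine content	0.270	0.283	0.270
Spleen	0.120	0.110	0.120
Stomach	0.110	0.106	0.110
Stomach content	0.180	0.180	0.180
Tooth	0.045	0.046	0.034
Thymus	0.029	0.028	0.029
Thyroid	0.017	0.017	0.017
Tongue	0.051	0.051	0.051
Trachea	0.007	0.007	0.007
Urinary bladder	0.030	0.032	0.030
Urinary bladder content	0.085	0.090	0.085
Uterus	0.070	0.067	0.070
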