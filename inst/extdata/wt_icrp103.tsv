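# ICRP Publication 103 tissue weighting factors.  `remainder` is the
# arithmetic-mean remainder tissue; the remainder member list is below the
# weight block, flagged by weight = NA.
tissue	w_T
red_marrow	0.12
colon	0.12
lung	0.12
stomach	0.12
breast	0.12
gonads	0.08
bladder	0.04
oesophagus	0.04
liver	0.04
thyroid	0.04
bone_surface	0.01
brain	0.01
salivary_glands	0.01
skin	0.01
remainder	0.12
adrenals	NA
extrathoracic_region	NA
gall_bladder	NA
heart	NA
kidneys	NA
lymphatic_nodes	NA
muscle	NA
oral_mucosa	NA
pancreas	NA
prostate_or_uterus	NA
small_intestine	NA
spleen	NA
thymus	NA
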