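# Published worked-example lesion summaries from a paediatric neuroblastoma
# FDG-PET study: per-lesion semi-quantitative parameters as printed, under
# the total-lesion and 40%-of-SUVmax threshold segmentations. MTV in mL,
# TLG in mL*SUV, AUC-CSH dimensionless. NA where the value was not printed.
lesion_id,pattern,suv_max,mtv_total,tlg_total,auccsh_total,mtv_40,tlg_40,auccsh_40
hom_example,homogeneous,NA,82.03,124.33,0.617,79.04,121.65,0.629
het_example,heterogeneous,NA,481.43,696.02,0.362,177.30,382.38,0.546
progressor,heterogeneous,3.5,196.23,272.08,0.387,NA,NA,NA
disease_free,homogeneous,4.17,243.44,555.22,0.542,NA,NA,NA
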