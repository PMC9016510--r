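pcg,category
hypertension,hypertension
hypertension_renal,hypertension
hypertension_combination,hypertension
mental,mental
depression,mental
psychosis,mental
pain,pain
neuropathic_pain,pain
asthma_copd,respiratory
cystic_fibrosis,respiratory
thyroid,thyroid
glaucoma,glaucoma
diabetes,diabetes
diabetes_complicated,diabetes
cancer,cancer
cancer_hormonal,cancer
parkinson,parkinson
cardiac,cardiac
heart_failure,cardiac
arrhythmia,cardiac
anticoagulation,cardiac
inflammatory,inflammatory
rheumatoid_arthritis,inflammatory
crohns_colitis,inflammatory
immune,immune
transplant,immune
hiv,hiv
other_mental,other_mental
dementia,other_mental
cholesterol,metabolic_other
gout,metabolic_other
osteoporosis,metabolic_other
epilepsy,metabolic_other
kidney_disease,metabolic_other
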