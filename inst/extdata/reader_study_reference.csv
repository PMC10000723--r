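kind,n_gt,kappa_two_sequence,kappa_two_sequence_low,kappa_two_sequence_high,kappa_synthetic,kappa_synthetic_low,kappa_synthetic_high,accuracy_two_sequence,accuracy_synthetic
bone_marrow_abnormality,61,0.73,0.67,0.78,0.74,0.67,0.82,81.2,82.2
spondylodiscitis_expansion,5,0.35,0.17,0.54,0.43,0.14,0.72,94.6,95.0
modic_type1,28,0.39,0.29,0.49,0.68,0.56,0.79,80.2,87.1
vertebral_fracture,21,0.77,0.71,0.84,0.77,0.68,0.87,91.6,92.1
cord_lesion,15,0.47,0.34,0.60,0.52,0.34,0.69,90.1,90.0
paravertebral_abnormality,25,0.67,0.59,0.75,0.73,0.62,0.83,88.1,88.6
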