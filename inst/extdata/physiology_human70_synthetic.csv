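tissue,V_total_L,V_residual_blood_L,V_ew_L,V_iw_L,Q_blood_L_per_h
adipose,18.2,0.182,2.52252,15.49548,15
bone,7.9,0.3239,2.65164,4.92446,15
brain,1.45,0.03045,0.29811,1.12144,36
gut,1.65,0.0165,0.45738,1.17612,52.5
heart,0.33,0.02013,0.09916,0.21071,15
kidney,0.31,0.0496,0.08854,0.17186,57
liver,1.82,0.3822,0.33069,1.10711,81
lung,0.53,0.1908,0.11533,0.22387,300
muscle,28.98,0.75348,3.38718,24.83934,60
pancreas,0.14,0.0084,0.03158,0.10002,3
skin,3.3,0.0627,1.29492,1.94238,21
spleen,0.19,0.0532,0.04104,0.09576,6
arterial_blood,1.53,,,,
venous_blood,3.37,,,,
portal_vein,0.30,,,,
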