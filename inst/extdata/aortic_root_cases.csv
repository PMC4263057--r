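subject_id,group,a_sinus,d_sinus,q_max,q_mean,v_max,a_orifice,orifice_ratio,compliance,distensibility,beta
C1,control,7.8,3.15,682,128,238,4.23,0.56,25.6,4.06,0.21
C2,control,10.1,3.58,400,62,209,4.58,0.52,25,2.6,0.26
P1,patient,7.7,3.13,551,99.8,240,2.91,0.48,9.3,1.35,0.52
P2,patient,8.8,3.34,650,107,336,2.95,0.39,12.4,1.62,0.35
P3,patient,6.8,3.0,597,98,340,2.47,0.38,18.6,2.61,0.32
P4,patient,8.5,3.28,473,81.4,342,3.61,0.42,10.2,1.24,0.52
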