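# closed-loop circulation model parameters
T = 1 # s
Ts1 = 0.29999999999999999 # s
Ts2 = 0.45000000000000001 # s
Tpwb = 0.92000000000000004 # s
Tpww = 0.089999999999999997 # s
Elv_max = 2.5 # mmHg/ml
Elv_min = 0.10000000000000001 # mmHg/ml
Vlv0 = 5 # ml
Ela_max = 0.25 # mmHg/ml
Ela_min = 0.14999999999999999 # mmHg/ml
Vla0 = 4 # ml
Erv_max = 1.1499999999999999 # mmHg/ml
Erv_min = 0.10000000000000001 # mmHg/ml
Vrv0 = 10 # ml
Era_max = 0.25 # mmHg/ml
Era_min = 0.14999999999999999 # mmHg/ml
Vra0 = 4 # ml
CQ_ao = 350 # ml/(s.mmHg^0.5)
CQ_mi = 400 # ml/(s.mmHg^0.5)
CQ_ti = 400 # ml/(s.mmHg^0.5)
CQ_po = 350 # ml/(s.mmHg^0.5)
R_sas = 0.0030000000000000001 # mmHg.s/ml
C_sas = 0.080000000000000002 # ml/mmHg
L_sas = 6.2000000000000003e-05 # mmHg.s^2/ml
R_sat = 0.050000000000000003 # mmHg.s/ml
C_sat = 1.6000000000000001 # ml/mmHg
L_sat = 0.0016999999999999999 # mmHg.s^2/ml
R_sar = 0.5 # mmHg.s/ml
R_scp = 0.52000000000000002 # mmHg.s/ml
R_svn = 0.074999999999999997 # mmHg.s/ml
C_svn = 20.5 # ml/mmHg
R_pas = 0.002 # mmHg.s/ml
C_pas = 0.17999999999999999 # ml/mmHg
L_pas = 5.1999999999999997e-05 # mmHg.s^2/ml
R_pat = 0.01 # mmHg.s/ml
C_pat = 3.7999999999999998 # ml/mmHg
L_pat = 0.0016999999999999999 # mmHg.s^2/ml
R_par = 0.050000000000000003 # mmHg.s/ml
R_pcp = 0.25 # mmHg.s/ml
R_pvn = 0.0060000000000000001 # mmHg.s/ml
C_pvn = 20.5 # ml/mmHg
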