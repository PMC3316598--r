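site,role,pi_o2,pi_o2_sem,pi_ni,pi_ni_sem,depth,phi_printed,phi_printed_sem
V278R1,protein,0.25,0.01,0.17,0.02,,0.31,0.02
T280R1,protein,0.27,0.05,0.53,0.03,,-0.68,0.03
K282R1,protein,0.26,0.03,0.19,0.01,,0.30,0.01
Y298R1,protein,0.38,0.02,1.18,1.11,,-1.15,0.01
T300R1,protein,0.21,0.04,1.00,0.10,,-1.57,0.01
K302R1,protein,0.22,0.01,1.12,0.04,,-1.66,0.02
E303R1,protein,0.21,0.04,0.66,0.03,,-1.19,0.01
I307R1,protein,0.17,0.01,0.77,0.09,,-1.50,0.01
E319R1,protein,0.17,0.01,0.81,0.24,,-1.52,0.01
R322R1,protein,0.31,0.03,0.29,0.04,,0.10,0.02
K323R1,protein,0.22,0.06,0.78,0.06,,-1.29,0.03
N325R1,protein,0.25,0.01,0.93,0.20,,-1.30,0.03
A346R1,protein,0.24,0.01,0.56,0.05,,-0.87,0.01
D347R1,protein,0.24,0.08,0.29,0.05,,-0.23,0.01
V351R1,protein,0.21,0.01,1.00,0.08,,-1.58,0.02
E352R1,protein,0.28,0.06,0.80,0.04,,-1.09,0.03
S364R1,protein,0.22,0.04,1.35,0.03,,-1.85,0.01
K373R1,protein,0.32,0.02,1.15,0.17,,-1.29,0.01
5-doxyl-PC,calibration,0.2324,0.02,0.20,0.02,-8,,
7-doxyl-PC,calibration,0.3644,0.02,0.20,0.02,-11,,
10-doxyl-PC,calibration,0.4919,0.02,0.20,0.02,-13,,
12-doxyl-PC,calibration,0.7716,0.02,0.20,0.02,-16,,
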