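system,host,set,dg_calc,dg_err,dg_exp
OAMe-G1,OAMe,gaff_refined,-6.36,0.39,-5.36
OAMe-G2,OAMe,gaff_refined,-6.76,0.41,-5.16
OAMe-G3,OAMe,gaff_refined,-5.44,0.56,-5.85
OAMe-G4,OAMe,gaff_refined,-3.64,1.63,-2.38
OAMe-G5,OAMe,gaff_refined,-3.45,0.34,-3.91
OAMe-G6,OAMe,gaff_refined,-4.28,0.34,-4.49
OAH-G1,OAH,gaff_refined,-6.07,0.35,-5.23
OAH-G2,OAH,gaff_refined,-5.08,0.72,-4.50
OAH-G3,OAH,gaff_refined,-5.92,0.58,-4.79
OAH-G4,OAH,gaff_refined,-11.85,0.61,-9.38
OAH-G5,OAH,gaff_refined,-4.80,0.46,-4.12
OAH-G6,OAH,gaff_refined,-5.52,0.64,-5.13
OAH-Gu2,OAH,gaff_refined,-9.59,0.66,-5.90
OAMe-G1,OAMe,opls_refined,-4.74,0.52,-5.36
OAMe-G2,OAMe,opls_refined,-7.94,0.56,-5.16
OAMe-G3,OAMe,opls_refined,-3.56,0.45,-5.85
OAMe-G4,OAMe,opls_refined,-0.36,0.58,-2.38
OAMe-G5,OAMe,opls_refined,-2.43,1.41,-3.91
OAMe-G6,OAMe,opls_refined,-5.30,0.70,-4.49
OAH-G1,OAH,opls_refined,-6.57,0.35,-5.23
OAH-G2,OAH,opls_refined,-5.83,0.57,-4.50
OAH-G3,OAH,opls_refined,-5.99,0.53,-4.79
OAH-G4,OAH,opls_refined,-11.03,0.61,-9.38
OAH-G5,OAH,opls_refined,-4.98,0.35,-4.12
OAH-G6,OAH,opls_refined,-5.94,0.38,-5.13
OAH-Gu2,OAH,opls_refined,-7.00,0.87,-5.90
OAMe-G1,OAMe,gaff_submitted,-2.56,NA,-5.36
OAMe-G2,OAMe,gaff_submitted,-2.79,NA,-5.16
OAMe-G3,OAMe,gaff_submitted,-0.84,NA,-5.85
OAMe-G4,OAMe,gaff_submitted,-0.09,NA,-2.38
OAMe-G5,OAMe,gaff_submitted,0.69,NA,-3.91
OAMe-G6,OAMe,gaff_submitted,0.05,NA,-4.49
OAH-G1,OAH,gaff_submitted,-3.08,NA,-5.23
OAH-G2,OAH,gaff_submitted,-2.91,NA,-4.50
OAH-G3,OAH,gaff_submitted,-2.26,NA,-4.79
OAH-G4,OAH,gaff_submitted,-7.94,NA,-9.38
OAH-G5,OAH,gaff_submitted,-1.32,NA,-4.12
OAH-G6,OAH,gaff_submitted,-3.33,NA,-5.13
OAH-Gu2,OAH,gaff_submitted,-5.90,NA,-5.90
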