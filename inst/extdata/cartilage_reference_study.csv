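protein,family,n_peptides,conc_fold,conc_diff_pmol_ug,conc_p,hl_fold,hl_diff_d,hl_p,abs_fold,abs_diff_pmol_mg_d,abs_p
ACAN,proteoglycan,4,1.96,0.286,0.0001,22.0,22100,0.6665,0.09,-2.58e-4,0.0001
ASPN,proteoglycan,2,1.24,0.0096,0.2389,0.54,-1440,0.3245,2.29,0.16e-4,0.0022
BGN,proteoglycan,6,0.76,-0.222,0.0057,1.52,880,0.5079,0.50,-2.67e-4,0.0001
DCN,proteoglycan,6,1.00,0.0022,0.9746,1.54,27,0.0022,0.65,-36.8e-4,0.0011
FMOD,proteoglycan,3,0.52,-0.544,0.0001,1.93,7150,0.8820,0.27,-1.07e-4,0.0001
FN1,proteoglycan,6,1.89,0.136,0.0009,2.27,110,0.0026,0.83,-2.94e-4,0.1129
LUM,proteoglycan,4,1.17,0.0704,0.3086,1.34,29,0.0325,0.88,-5.85e-4,0.3585
OGN,proteoglycan,2,0.79,-0.0226,0.1285,88.0,137000,0.9411,0.01,-0.69e-4,0.0001
PRELP,proteoglycan,4,0.64,-0.260,0.0001,1.70,270,0.0749,0.38,-11.5e-4,0.0001
PRG4,proteoglycan,4,2.02,0.0759,0.0004,1.72,24,0.0001,1.18,3.96e-4,0.2006
COL1A1,collagen,2,0.85,-0.0936,0.1261,45.0,135000,0.8276,0.02,-2.05e-4,0.0001
COL2A1,collagen,4,0.64,-0.248,0.0001,NA,NA,NA,0,-0.053e-4,0.0001
COL6A1,collagen,12,0.98,0.0116,0.8726,NA,NA,NA,0.98,-0.00042e-4,0.8726
COL6A2,collagen,7,1.01,0.0056,0.9210,2,121000,0.9105,0.51,-0.018e-4,0.0001
COL6A3,collagen,15,0.85,-0.0562,0.2226,1.57,6000,0.7787,0.54,-0.165e-4,0.0001
COL9A1,collagen,4,0.86,-0.0066,0.0469,NA,NA,NA,NA,NA,NA
COL11A1,collagen,2,0.76,-0.0067,0.0053,NA,NA,NA,NA,NA,NA
COL12A1,collagen,4,0.73,-0.0256,0.0011,NA,NA,NA,0,-0.0069e-4,0.0001
CHAD,ecm_related,4,0.76,-0.174,0.0229,46.0,277000,0.6766,0.17,-1.20e-4,0.0001
CHIL3,ecm_related,2,0.38,-0.0387,0.0001,1.08,8,0.7965,0.35,-4.01e-4,0.0001
CILP,ecm_related,3,0.57,-0.0098,0.0001,1.69,91,0.3906,0.35,-1.21e-4,0.0001
CLU,ecm_related,3,2.37,0.100,0.0001,2.93,139,0.0006,0.81,-1.96e-4,0.0432
COMP,ecm_related,2,0.62,-0.184,0.0001,2.33,117,0.0045,0.26,-40.4e-4,0.0001
LMNA,ecm_related,7,0.91,-0.0041,0.4943,1.12,8,0.3780,0.82,-1.20e-4,0.1279
MATN1,ecm_related,2,0.56,-0.0058,0.0001,NA,NA,NA,NA,NA,NA
MATN3,ecm_related,4,0.60,-0.0171,0.0011,1.56,114,0.1153,0.38,-1.30e-4,0.0001
MFGE8,ecm_related,5,0.43,-0.530,0.0001,0.78,-55,0.7833,0.55,-16.7e-4,0.0001
SPP1,ecm_related,3,0.59,-0.074,0.0001,NA,NA,NA,0,-0.017e-4,0.0001
THBS1,ecm_related,3,0.72,-0.0278,0.0186,3.67,660,0.1650,0.20,-3.25e-4,0.0001
VTN,ecm_related,3,1.11,0.0168,0.4339,2.84,436,0.0379,0.39,-4.10e-4,0.0001
ACTBG,cellular,2,0.61,-0.200,0.0014,NA,NA,NA,NA,NA,NA
HSP90B,cellular,2,0.82,-0.0109,0.1163,NA,NA,NA,NA,NA,NA
HSPA1A,cellular,2,0.57,-0.0545,0.0020,NA,NA,NA,NA,NA,NA
HSPA5,cellular,2,0.69,-0.0272,0.0081,NA,NA,NA,NA,NA,NA
PPIA,cellular,2,0.54,-0.0130,0.0004,NA,NA,NA,NA,NA,NA
TUBA,cellular,2,0.51,-0.0837,0.0001,NA,NA,NA,NA,NA,NA
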