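session_id,patient_id,sex,age,weight_kg,activity_mbq,scan_time_s,activity_algo_mbq,scan_time_algo_s,ed_ref_msv,acr_ref,acr_algo
S1,P01,M,19,87,362,1211,289,1465,5.792,0.0687,0.0549
S1,P02,F,29,75,268,1113,214,1335,4.288,0.0592,0.0473
S1,P03,M,51,70,283,1165,226,1398,4.528,0.0223,0.0178
S1,P04,M,63,88,277,1217,277,1217,4.432,0.0157,0.0157
S1,P05,F,67,55,241,956,241,956,3.856,0.0146,0.0146
S1,P06,F,70,90,271,1124,271,1124,4.336,0.0149,0.0149
S1,P07,M,76,70,352,1193,352,1193,5.632,0.0139,0.0139
S1,P08,M,77,55,230,1188,276,950,3.68,0.0089,0.0106
S1,P09,M,79,64,202,1338,242,1070,3.232,0.0074,0.0088
S1,P10,F,81,58,247,1315,296,1052,3.952,0.0093,0.0111
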