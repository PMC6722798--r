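case_id,mean_intensity,percent_positive
case_01,0.00015836,55
case_02,0.00866000,82
case_03,0.00002071,14
case_04,0.00340193,78
case_05,0.00838533,73
case_06,0.00037859,73
case_07,0.00006853,27
case_08,0,0
case_09,0.0001780,65
case_10,0.0055402,98
case_11,0.0000863,57
case_12,0.0018610,99
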