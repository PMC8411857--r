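"prototype","td_01","td_02","td_03","td_04","td_05","td_06","td_07","td_08","td_09","td_10","td_11","td_12","td_13","td_14","td_15","td_16","td_17","td_18","td_19","td_20","td_21","td_22","td_23","td_24","td_25","td_26","td_27","td_28","td_29","td_30","td_31","td_32","td_33","td_34","td_35","td_36","td_37","td_38","td_39","td_40","td_41","td_42","td_43","td_44","td_45","td_46","td_47","td_48","td_49","td_50","td_51","td_52","td_53","td_54"
"normal",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"general_depression_mild",-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3,-3
"general_depression_severe",-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20,-20
"blind_spot_enlargement",0,0,0,0,0,0,0,0,0,0,0,-12,0,0,0,0,0,0,-12,-30,-12,0,0,0,0,0,0,-12,-30,-12,0,0,0,0,0,0,0,-12,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"arcuate_superior",-5.122428,-8.186915,-8.186915,-5.122428,-8.186915,-15.856012,-17.967613,-17.967613,-15.856012,-8.186915,-5.122428,-15.856012,-16.200108,-9.680034,-9.680034,-16.200108,-15.856012,-5.122428,-8.186915,-17.967613,-9.680034,-1.696764,-1.696764,-9.680034,-17.967613,-8.186915,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"arcuate_inferior",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-8.186915,-17.967613,-9.680034,-1.696764,-1.696764,-9.680034,-17.967613,-8.186915,0,-5.122428,-15.856012,-16.200108,-9.680034,-9.680034,-16.200108,-15.856012,-5.122428,-8.186915,-15.856012,-17.967613,-17.967613,-15.856012,-8.186915,-5.122428,-8.186915,-8.186915,-5.122428
"nasal_defect",0,0,0,0,0,0,0,0,0,-15,0,0,0,0,0,0,-15,-15,0,0,0,0,0,0,-15,-15,-15,0,0,0,0,0,0,-15,-15,-15,0,0,0,0,0,0,-15,-15,0,0,0,0,0,-15,0,0,0,0
"temporal_hemianopia",-22,-22,0,0,-22,-22,-22,0,0,0,-22,-22,-22,-22,0,0,0,0,-22,-22,-22,-22,0,0,0,0,0,-22,-22,-22,-22,0,0,0,0,0,-22,-22,-22,-22,0,0,0,0,-22,-22,-22,0,0,0,-22,-22,0,0
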