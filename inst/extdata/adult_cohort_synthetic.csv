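"id","role","age_years","sex","fh_first_degree_pcvd","fh_first_degree_hyperlipidemia","fh_relative_fh_diagnosis","fh_child_high_ldl","ph_premature_cad","ph_premature_cerebral_peripheral","sign_tendon_xanthoma","sign_relative_tendon_xanthoma","sign_arcus_under_45","sign_xanthelasma","pre_tc","pre_ldl","pre_hdl","pre_tg","on_ldl","peak_ldl","regimen","genetic_confirmed","excluded_alternative_diagnosis"
"P01","proband",41,"F",TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,12.38,10.8,1,1.28,4.86,11.27,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P02","proband",42,"M",TRUE,TRUE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,11.78,10.2,1,1.28,4.59,10.67,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P03","proband",43,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,11.38,9.8,1,1.28,4.41,10.27,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P04","proband",44,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,11.08,9.5,1,1.28,4.27,9.97,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P05","proband",45,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.78,9.2,1,1.28,4.14,9.67,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P06","proband",46,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.58,9,1,1.28,4.05,9.47,"rosuvastatin:20;ezetimibe:10",TRUE,FALSE
"P07","proband",47,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.48,8.9,1,1.28,4,9.37,"atorvastatin:80",TRUE,FALSE
"P08","proband",48,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.38,8.8,1,1.28,3.96,9.27,"atorvastatin:80",TRUE,FALSE
"P09","proband",49,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.28,8.7,1,1.28,3.91,9.17,"atorvastatin:80",TRUE,FALSE
"P10","proband",50,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.18,8.6,1,1.28,3.87,9.07,"atorvastatin:80",TRUE,FALSE
"P11","proband",51,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.08,8.5,1,1.28,3.82,8.97,"rosuvastatin:20",TRUE,FALSE
"P12","proband",52,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.88,8.3,1,1.28,3.73,8.77,"rosuvastatin:20",TRUE,FALSE
"P13","proband",53,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.68,8.1,1,1.28,3.64,8.57,"rosuvastatin:20",TRUE,FALSE
"P14","proband",54,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.38,7.8,1,1.28,3.51,8.27,"rosuvastatin:20",TRUE,FALSE
"P15","proband",55,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,8.88,7.3,1,1.28,3.28,7.77,"atorvastatin:40",TRUE,FALSE
"P16","proband",56,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,8.4,6.82,1,1.28,3.07,7.29,"atorvastatin:40",TRUE,FALSE
"P17","cascade_relative",57,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.98,9.4,1,1.28,4.23,9.56,"atorvastatin:40",TRUE,FALSE
"P18","cascade_relative",58,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.58,9,1,1.28,4.05,9.16,"atorvastatin:40",TRUE,FALSE
"P19","cascade_relative",59,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.18,8.6,1,1.28,3.87,8.76,"rosuvastatin:10",TRUE,FALSE
"P20","cascade_relative",60,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.98,8.4,1,1.28,3.78,8.56,"rosuvastatin:10",TRUE,FALSE
"P21","cascade_relative",61,"F",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.6,8.02,1,1.28,5.61,8.18,"simvastatin:10",TRUE,FALSE
"P22","cascade_relative",62,"M",TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,6.78,5.2,1,1.28,2.34,5.36,"atorvastatin:40",TRUE,FALSE
"P23","cascade_relative",63,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,6.18,4.6,1,1.28,2.07,4.76,"rosuvastatin:20",TRUE,FALSE
"P24","cascade_relative",64,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,5.88,4.3,1,1.28,1.93,4.46,"rosuvastatin:5",TRUE,FALSE
"P25","cascade_relative",65,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,5.98,4.4,1,1.28,,4.56,"",TRUE,FALSE
"P26","cascade_relative",66,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,5.78,4.2,1,1.28,,4.36,"",TRUE,FALSE
"N01","proband",45,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10.5,7.4,1.3,3.96,4.81,11.5,"simvastatin:20",FALSE,FALSE
"N02","proband",50,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,10,6.7,1.3,4.4,4.76,10.5,"pravastatin:40",FALSE,FALSE
"N03","proband",55,"M",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,9.5,5.49,2,4.42,3.95,9.5,"simvastatin:10",FALSE,FALSE
"N04","cascade_relative",48,"F",FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,6.4,4.66,1.2,1.19,2.1,4.76,"rosuvastatin:20",FALSE,FALSE
"N05","cascade_relative",52,"M",FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,5.5,3.7,1.3,1.1,2.59,3.8,"simvastatin:10",FALSE,FALSE
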