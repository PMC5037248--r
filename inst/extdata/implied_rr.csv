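factor,outcome,stratum,pe,rr,ci_lower,ci_upper,log_se,provenance
smoking,chd,men,0.649,1.5164,1.3001,1.7521,0.07612,derived
smoking,chd,women,0.021,1.6761,1.3357,2.121,0.11797,derived
elevated_cholesterol,chd,women,0.396,1.5468,1.1959,1.9483,0.1245,derived
diabetes,chd,men,0.056,1.7829,1.4204,2.2006,0.11168,derived
diabetes,chd,women,0.077,2.5561,1.6979,3.7739,0.20375,derived
smoking,all_stroke,men,0.649,1.3089,1.2042,1.4295,0.04375,derived
smoking,all_stroke,women,0.021,1.2874,1.0954,1.481,0.07694,derived
elevated_cholesterol,all_stroke,women,0.396,1.1872,1.0333,1.3608,0.07023,derived
diabetes,all_stroke,men,0.056,1.7054,1.4767,1.9398,0.06959,derived
diabetes,all_stroke,women,0.077,1.9925,1.527,2.5236,0.12816,derived
smoking,ischaemic_stroke,men,0.649,1.5164,1.3067,1.7693,0.07732,derived
smoking,ischaemic_stroke,women,0.021,1.2874,1.0477,1.6272,0.11231,derived
elevated_cholesterol,ischaemic_stroke,women,0.396,1.2837,1.0101,1.6274,0.12167,derived
diabetes,ischaemic_stroke,men,0.056,1.9994,1.6669,2.4688,0.1002,derived
diabetes,ischaemic_stroke,women,0.077,1.829,1.1577,2.8893,0.23331,derived
smoking,haemorrhagic_stroke,men,0.649,1.1827,1.0187,1.3756,0.07662,derived
smoking,haemorrhagic_stroke,women,0.021,1.2874,1.0477,1.6761,0.11987,derived
elevated_cholesterol,haemorrhagic_stroke,women,0.396,1.1526,0.8797,1.4882,0.13412,derived
diabetes,haemorrhagic_stroke,men,0.056,1.4204,1.0897,1.8024,0.12837,derived
diabetes,haemorrhagic_stroke,women,0.077,2.1909,1.265,3.6789,0.27233,derived
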