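factor,outcome,stratum,par,ci_lower,ci_upper,provenance
smoking,chd,men,25.1,16.3,32.8,printed
smoking,chd,women,1.4,0.7,2.3,printed
smoking,chd,age_lt55,20.3,13.2,27.9,printed
smoking,chd,age_ge55,10.6,5.0,15.7,printed
hypertension,chd,men,19.7,16.3,23.6,printed
hypertension,chd,women,25.3,18.1,32.6,printed
hypertension,chd,age_lt55,32.9,28.7,37.5,printed
hypertension,chd,age_ge55,33.1,26.6,39.0,printed
elevated_cholesterol,chd,men,19.0,14.2,23.9,printed
elevated_cholesterol,chd,women,17.8,7.2,27.3,printed
elevated_cholesterol,chd,age_lt55,25.3,20.0,31.6,printed
elevated_cholesterol,chd,age_ge55,17.7,8.5,25.7,printed
excess_body_weight,chd,men,9.4,6.0,12.7,printed
excess_body_weight,chd,women,10.4,2.2,19.2,printed
excess_body_weight,chd,age_lt55,19.6,14.1,25.1,printed
excess_body_weight,chd,age_ge55,3.3,−0.3,7.9,printed
diabetes,chd,men,4.2,2.3,6.3,printed
diabetes,chd,women,10.7,5.1,17.6,printed
diabetes,chd,age_lt55,7.9,5.3,11.0,printed
diabetes,chd,age_ge55,8.4,3.9,13.8,printed
smoking,all_stroke,men,16.7,11.7,21.8,printed
smoking,all_stroke,women,0.6,0.2,1.0,printed
smoking,all_stroke,age_lt55,11.1,6.2,15.4,printed
smoking,all_stroke,age_ge55,3.7,0.5,6.7,printed
hypertension,all_stroke,men,37.2,34.8,39.6,printed
hypertension,all_stroke,women,38.9,34.7,42.9,printed
hypertension,all_stroke,age_lt55,49.0,46.5,51.6,printed
hypertension,all_stroke,age_ge55,52.9,49.6,56.3,printed
elevated_cholesterol,all_stroke,men,3.9,1.1,7.0,printed
elevated_cholesterol,all_stroke,women,6.9,1.3,12.5,printed
elevated_cholesterol,all_stroke,age_lt55,10.3,7.0,13.7,printed
elevated_cholesterol,all_stroke,age_ge55,2.2,−3.7,7.5,printed
excess_body_weight,all_stroke,men,5.4,3.2,7.4,printed
excess_body_weight,all_stroke,women,8.2,3.4,12.5,printed
excess_body_weight,all_stroke,age_lt55,14.6,11.1,17.9,printed
excess_body_weight,all_stroke,age_ge55,0.4,−1.8,2.8,printed
diabetes,all_stroke,men,3.8,2.6,5.0,printed
diabetes,all_stroke,women,7.1,3.9,10.5,printed
diabetes,all_stroke,age_lt55,6.3,4.8,7.9,printed
diabetes,all_stroke,age_ge55,5.8,2.8,8.8,printed
smoking,ischaemic_stroke,men,25.1,16.6,33.3,printed
smoking,ischaemic_stroke,women,0.6,0.1,1.3,printed
smoking,ischaemic_stroke,age_lt55,14.4,6.8,23.1,printed
smoking,ischaemic_stroke,age_ge55,7.1,2.1,12.6,printed
hypertension,ischaemic_stroke,men,29.3,25.1,33.0,printed
hypertension,ischaemic_stroke,women,37.3,30.8,43.9,printed
hypertension,ischaemic_stroke,age_lt55,38.2,33.5,43.4,printed
hypertension,ischaemic_stroke,age_ge55,53.2,47.6,58.3,printed
elevated_cholesterol,ischaemic_stroke,men,10.1,5.6,15.0,printed
elevated_cholesterol,ischaemic_stroke,women,10.1,0.4,19.9,printed
elevated_cholesterol,ischaemic_stroke,age_lt55,19.3,13.6,24.9,printed
elevated_cholesterol,ischaemic_stroke,age_ge55,2.6,−5.4,11.6,printed
excess_body_weight,ischaemic_stroke,men,10.6,7.2,14.2,printed
excess_body_weight,ischaemic_stroke,women,15.1,7.7,22.2,printed
excess_body_weight,ischaemic_stroke,age_lt55,22.7,17.4,28.6,printed
excess_body_weight,ischaemic_stroke,age_ge55,4.4,0.9,8.1,printed
diabetes,ischaemic_stroke,men,5.3,3.6,7.6,printed
diabetes,ischaemic_stroke,women,6.0,1.2,12.7,printed
diabetes,ischaemic_stroke,age_lt55,8.3,5.7,11.3,printed
diabetes,ischaemic_stroke,age_ge55,7.3,2.6,12.7,printed
smoking,haemorrhagic_stroke,men,10.6,1.2,19.6,printed
smoking,haemorrhagic_stroke,women,0.6,0.1,1.4,printed
smoking,haemorrhagic_stroke,age_lt55,4.4,−2.9,10.9,printed
smoking,haemorrhagic_stroke,age_ge55,3.3,−1.7,8.8,printed
hypertension,haemorrhagic_stroke,men,47.3,43.1,51.3,printed
hypertension,haemorrhagic_stroke,women,46.6,39.7,53.2,printed
hypertension,haemorrhagic_stroke,age_lt55,61.3,57.1,65.2,printed
hypertension,haemorrhagic_stroke,age_ge55,56.2,50.8,61.6,printed
elevated_cholesterol,haemorrhagic_stroke,men,−2.6,−7.5,2.3,printed
elevated_cholesterol,haemorrhagic_stroke,women,5.7,−5.0,16.2,printed
elevated_cholesterol,haemorrhagic_stroke,age_lt55,1.1,−4.2,6.6,printed
elevated_cholesterol,haemorrhagic_stroke,age_ge55,2.8,−7.5,12.9,printed
excess_body_weight,haemorrhagic_stroke,men,3.8,0.7,7.6,printed
excess_body_weight,haemorrhagic_stroke,women,1.9,−5.4,9.6,printed
excess_body_weight,haemorrhagic_stroke,age_lt55,10.9,5.1,16.8,printed
excess_body_weight,haemorrhagic_stroke,age_ge55,−1.2,−5.0,3.1,printed
diabetes,haemorrhagic_stroke,men,2.3,0.5,4.3,printed
diabetes,haemorrhagic_stroke,women,8.4,2.0,17.1,printed
diabetes,haemorrhagic_stroke,age_lt55,4.9,2.5,7.8,printed
diabetes,haemorrhagic_stroke,age_ge55,2.7,−2.6,9.7,printed
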