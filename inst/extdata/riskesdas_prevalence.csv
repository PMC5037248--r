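factor,stratum,value,provenance
smoking,men,0.649,printed
smoking,women,0.021,printed
hypertension,men,,unavailable
hypertension,women,,unavailable
elevated_cholesterol,men,,unavailable
elevated_cholesterol,women,0.396,printed
excess_body_weight,men,,unavailable
excess_body_weight,women,,unavailable
diabetes,men,0.056,printed
diabetes,women,0.077,printed
smoking,age_lt55,,unavailable
smoking,age_ge55,,unavailable
hypertension,age_lt55,,unavailable
hypertension,age_ge55,,unavailable
elevated_cholesterol,age_lt55,,unavailable
elevated_cholesterol,age_ge55,,unavailable
excess_body_weight,age_lt55,,unavailable
excess_body_weight,age_ge55,,unavailable
diabetes,age_lt55,,unavailable
diabetes,age_ge55,,unavailable
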