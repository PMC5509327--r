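study_id,ethnicity,snp_id,risk_allele,raf_case,raf_control,n_case,n_control,case_hom_risk,case_het,case_hom_other,control_hom_risk,control_het,control_hom_other,reported_or,or_ci_low,or_ci_high,hwe_ok
BouatiaNaji2008_European,Caucasian,rs560887,G,NA,0.70,2792,4073,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Reiling2009_NewHoorn,Caucasian,rs560887,G,NA,0.692,2628,2041,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Rose2009_Inter99,Caucasian,rs560887,G,NA,0.689,1963,4913,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Takeuchi2009_Japanese,Asian,rs560887,G,NA,0.971,5629,6406,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Takeuchi2009_SriLankan,Asian,rs560887,G,NA,0.907,599,515,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Prokopenko2009_DGI,Caucasian,rs560887,G,NA,NA,1464,1467,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_KORA,Caucasian,rs560887,G,NA,NA,433,1438,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_Rotterdam,Caucasian,rs560887,G,NA,NA,1178,4761,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_WTCCC_T2D,Caucasian,rs560887,G,NA,NA,1924,2938,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_CCC,Caucasian,rs560887,G,NA,NA,512,499,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Prokopenko2009_ADDITION_ELY,Caucasian,rs560887,G,NA,NA,852,1593,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Dupuis2010_MAGIC,Caucasian,rs560887,G,NA,0.70,40655,87022,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Rees2011_UKADS,Asian,rs560887,G,NA,0.82,857,417,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Rees2011_DGP,Asian,rs560887,G,NA,0.84,821,1167,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
AlDaghri2017_RiyadhCohort,Caucasian,rs560887,G,NA,0.81,185,377,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Hu2008_Shanghai,Asian,rs16856187,C,NA,0.285,1876,1800,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Hu2010_Shanghai,Asian,rs16856187,C,NA,0.294,3410,3412,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
Tam2010_HongKong,Asian,rs16856187,C,NA,0.298,1342,1644,NA,NA,NA,NA,NA,NA,NA,NA,NA,yes
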