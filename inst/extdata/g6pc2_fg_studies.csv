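study_id,ethnicity,snp_id,risk_allele,raf,n,hwe_ok,beta,beta_se,beta_ci_low,beta_ci_high,beta_p,n_hom_risk,mean_hom_risk,sd_hom_risk,n_het,mean_het,sd_het,n_hom_other,mean_hom_other,sd_hom_other
Reiling2009_NewHoorn,Caucasian,rs560887,G,0.693,2225,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_CoLaus,Caucasian,rs560887,G,0.72,5000,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_Framingham,Caucasian,rs560887,G,0.70,6479,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_Rotterdam,Caucasian,rs560887,G,0.69,2058,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Prokopenko2009_Sardinia,Caucasian,rs560887,G,0.63,4305,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Takeuchi2009_Japanese,Asian,rs560887,G,0.97,4813,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Takeuchi2009_SriLankan,Asian,rs560887,G,0.91,2319,no,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Chambers2009_IndianAsian,Asian,rs560887,G,0.85,5089,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Chambers2009_EuropeanWhites,Caucasian,rs560887,G,0.69,4462,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
BouatiaNaji2010_Haguenau,Caucasian,rs560887;rs573225,G;A,NA;NA,1201,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
BouatiaNaji2010_DESIR,Caucasian,rs560887;rs573225,G;A,NA;NA,3483,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
BouatiaNaji2010_NFBC86,Caucasian,rs560887;rs573225,G;A,NA;NA,4372,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
BouatiaNaji2010_ObeseChildren,Caucasian,rs560887;rs573225,G;A,NA;NA,476,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Ramos2010_HUFS,African-American,rs560887,G,0.957,927,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Renstrom2010_GLACIER,Caucasian,rs560887,G,0.71,1630,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Dupuis2010_MAGIC,Caucasian,rs560887,G,0.70,76558,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Barker2011_FRENCHControls,Caucasian,rs560887,G,0.70,634,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Barker2011_EYHS,Caucasian,rs560887,G,0.70,1934,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Barker2011_FRENCHCases,Caucasian,rs560887,G,0.70,581,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Barker2011_Raine,Caucasian,rs560887,G,0.70,1045,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Barker2011_ALSPAC,Caucasian,rs560887,G,0.70,1736,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Rees2011_SouthAsians,Asian,rs560887,G,0.84,1163,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Torvik2012_CAU,Caucasian,rs560887,G,0.72,2349,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Torvik2012_CHN,Asian,rs560887,G,0.97,664,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Torvik2012_AFA,African-American,rs560887,G,0.93,1366,no,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Torvik2012_HIS,Caucasian,rs560887,G,0.86,1171,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Baerenwald2013_DESIRCohort,Caucasian,rs560887;rs573225,G;A,0.695;0.670,4220,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Zheng2015_Caucasians,Caucasian,rs560887,G,0.723,336,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Zheng2015_Hispanics,Caucasian,rs560887,G,0.834,205,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Zheng2015_AfricanAmericans,African-American,rs560887,G,0.934,211,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Horikoshi2015_1000G,Caucasian,rs560887,G,0.69,40091,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Langlois2016_MexicanChildren,mixed,rs560887,G,0.913,1421,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Tam2010_HealthyAdults,Asian,rs16856187,A,0.303,583,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Tam2010_HealthyAdolescents,Asian,rs16856187,A,0.299,1061,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Hu2008_Shanghai,Asian,rs16856187,A,0.303,1800,yes,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
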