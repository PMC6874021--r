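trial_id,pub_year,update_years,regimen_a,regimen_b,n_total,endpoint,p_value,effect_measure,effect_value,is_primary,favored_arm
T01,1984,,HU,BUS,440,overall survival,0.04,MEDIAN_RATIO,1.3,TRUE,A
T02,1994,,IFNA,HU,580,overall survival,0.01,HAZARD_RATIO,0.7,TRUE,A
T03,1997,,IFNA-LoDAC,IFNA,720,overall survival,0.02,HAZARD_RATIO,0.76,TRUE,A
T04,2003,2009,IMAT,IFNA-LoDAC,1106,event-free survival,0.001,HAZARD_RATIO,0.47,TRUE,A
T04,2003,2009,IMAT,IFNA-LoDAC,1106,overall survival,0.08,HAZARD_RATIO,0.8,FALSE,A
T05,2010,,DAS,IMAT,519,complete cytogenetic response,0.001,ODDS_RATIO,1.8,TRUE,A
T06,2010,2014,NIL,IMAT,846,major molecular response,0.001,ODDS_RATIO,2.2,TRUE,A
T07,2012,,HD-IMAT,IMAT,420,major molecular response,0.03,ODDS_RATIO,1.6,TRUE,A
T08,2013,,BOS,IMAT,502,complete cytogenetic response,0.6,NONINFERIORITY,1.05,TRUE,NONE
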