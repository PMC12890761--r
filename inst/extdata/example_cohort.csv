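patient_id,index_date,age,sex,ethnicity,bmi,waist_circumference,sbp,dbp,egfr,acr,hba1c,phosphorus,fgf23,diabetes_duration,smoking,hypertension,cvd,medication_compliance,followup_months,event,censor_reason
EX001,2019-02,62,female,saudi,33.5,105,142,82,95,14,8.2,3.7,52.1,12,never,TRUE,FALSE,8,48,FALSE,none
EX002,2019-07,55,male,saudi,29.1,98,128,76,72,28,7.4,3.9,61.0,8,former,FALSE,FALSE,9,24,TRUE,none
EX003,2020-03,71,female,saudi,35.8,112,151,79,48,110,,4.1,88.4,19,never,TRUE,TRUE,6,40,FALSE,none
EX004,2021-01,47,male,non_saudi,27.3,,135,84,102,9,6.9,3.4,41.2,3,current,FALSE,FALSE,10,30,FALSE,administrative
EX005,2021-09,66,female,saudi,31.0,101,146,77,37,260,9.6,4.4,120.5,22,never,TRUE,FALSE,5,18,FALSE,death
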