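# run 48ac1e37173630b12a9ae1554297cdfc
person_id,index_date,age_years,is_male,egfr,acr_mgg,albuminuria_source,diabetes,hypertension,n_antihypertensives_6mo,calendar_period,followup_days,event,risk_published,refer_kdigo2012
1,2010-01-01,75.00068446,FALSE,35.48297402,100.00,acr,FALSE,TRUE,0,period1,1,krt,0.05103668176,FALSE
2,2010-01-01,80.00000000,TRUE,44.52842129,60.00,acr,TRUE,TRUE,1,period1,2,death,0.01727199943,FALSE
3,2010-01-01,70.00136893,FALSE,37.25655314,40.00,acr,FALSE,FALSE,0,period1,3,censored,0.03125272645,FALSE
4,2010-01-01,68.00000000,TRUE,50.12622754,250.00,acr,FALSE,TRUE,0,period1,4,krt,0.02289043843,FALSE
5,2010-01-01,82.00136893,FALSE,33.03371522,30.00,acr,FALSE,FALSE,0,period1,5,censored,0.03368864603,FALSE
7,2010-06-01,72.99931554,FALSE,34.06695807,350.00,acr,TRUE,TRUE,4,period1,1826,censored,0.10664167037,TRUE
9,2010-03-11,75.02806297,TRUE,47.74814681,500.00,dipstick,FALSE,TRUE,0,period1,1826,censored,0.03472136508,TRUE
10,2010-04-01,79.00068446,FALSE,33.26185150,114.92,pcr,FALSE,TRUE,0,period1,1736,censored,0.06331213835,FALSE
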