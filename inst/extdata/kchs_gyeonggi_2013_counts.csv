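covariate,level,n_nonobese,n_obese
gender,male,24536,11585
gender,female,33696,8197
age_group,19-39,21251,5823
age_group,40-59,24285,9162
age_group,60+,12696,4797
education,<=high school,30843,11685
education,>=college,27389,8097
household_income,<2793 USD,23765,8460
household_income,>=2793 USD,34467,11142
job,nonmanual,15749,5379
job,manual,19466,7794
job,other,23017,6609
marital_status,with spouse,45959,16158
marital_status,without spouse,12273,3624
smoking,never,38108,10510
smoking,former,8158,4082
smoking,current,11966,5190
drinking,never,8200,2710
drinking,former,6828,2303
drinking,current,43204,14769
sleeping_duration,<7h,27302,10292
sleeping_duration,>=7h,30930,9490
mvpa,no,20361,7249
mvpa,yes,37871,12533
diet,high sodium,14463,6094
diet,middle sodium,28438,9387
diet,low sodium,15331,4301
driving,yes,31921,12248
driving,no,26311,7534
subjective_health,poor,7908,3534
subjective_health,good,50324,16248
stress,no,42009,13443
stress,yes,16223,6339
depressive_symptoms,no,54312,18408
depressive_symptoms,yes,3920,1374
chronic_illnesses,0,42308,10930
chronic_illnesses,1,9584,4489
chronic_illnesses,2+,6340,4363
dist_pa_m,T1,20451,6425
dist_pa_m,T2,22396,7742
dist_pa_m,T3,15385,5615
dist_park_m,T1,21117,6683
dist_park_m,T2,20666,6957
dist_park_m,T3,16449,6142
dist_transit_m,T1,19550,6220
dist_transit_m,T2,22519,7804
dist_transit_m,T3,16163,5758
pop_density,T1,15100,5725
pop_density,T2,22652,7613
pop_density,T3,20480,6444
intersection_density,T1,14853,5281
intersection_density,T2,21861,7549
intersection_density,T3,21518,6952
lum,T1,19801,6326
lum,T2,19613,6675
lum,T3,18818,6781
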