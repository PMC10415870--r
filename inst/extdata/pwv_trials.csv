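study_id,treatment,n,change_mean,change_sd,baseline_mean,baseline_sd,final_mean,final_sd,population,duration_weeks
Christoph,TZD,27,0.7,2.1,12.9,3.5,NA,NA,CAD,36
Christoph,placebo,27,0.5,2.1,13.9,3.6,NA,NA,CAD,36
Antonio,SGLT2i,42,-0.6,1.4,6.2,1.6,NA,NA,T2DM,24
Antonio,placebo,42,0.6,1.2,6,1,NA,NA,T2DM,24
Ikonomidis,GLP1RA,40,-1.1,2.4,11.6,2.8,NA,NA,T2DM,48
Ikonomidis,SGLT2i,40,-1.1,2.5,12,2.8,NA,NA,T2DM,48
Stakos,TZD,40,1.1,0.4,NA,NA,NA,NA,T2DM,48
Stakos,placebo,97,0.7,0.4,NA,NA,NA,NA,T2DM,48
Lambadiari,GLP1RA,30,-0.6,2.8,11.8,2.5,NA,NA,T2DM,24
Lambadiari,metformin,30,-0.2,3.2,10.3,3.3,NA,NA,T2DM,24
Tuttolomondo,GLP1RA,56,-0.3,0.8,11.2,0.9,NA,NA,T2DM,36
Tuttolomondo,metformin,56,0.1,0.7,10.9,0.8,NA,NA,T2DM,36
Kato,TZD,25,0.08,0.4,15.4,0.4,NA,NA,T2DM,12
Kato,metformin,25,0.01,0.4,14.7,0.4,NA,NA,T2DM,12
Papadopoulou,SGLT2i,43,-0.2,1.1,8.8,1.1,NA,NA,T2DM,12
Papadopoulou,placebo,42,0.01,1.3,8.7,1.3,NA,NA,T2DM,12
deBoer,DPP4i,22,-0.4,0.3,8.7,0.3,NA,NA,T2DM,26
deBoer,placebo,22,0.4,0.3,8.8,0.3,NA,NA,T2DM,26
Kolwelter,DPP4i,48,-0.3,1.6,9.6,1.5,NA,NA,CHF,12
Kolwelter,placebo,26,0.3,1.7,9,1.6,NA,NA,CHF,12
Zografou,DPP4i,32,-0.3,1.5,8.6,2.1,NA,NA,T2DM,24
Zografou,metformin,32,0.2,1.8,8.9,2,NA,NA,T2DM,24
Paiman,GLP1RA,22,0.2,2.1,8.8,2.4,NA,NA,T2DM,26
Paiman,placebo,25,-0.2,1.7,8.3,2.4,NA,NA,T2DM,26
Kim,TZD,45,-0.9,2.5,14.8,2.6,NA,NA,pre-T2DM,12
Kim,placebo,40,0.02,2,14.4,2.3,NA,NA,pre-T2DM,12
Bjornstad,metformin,24,-1.1,1.2,NA,NA,NA,NA,T1DM,12
Bjornstad,placebo,21,4.1,1.6,NA,NA,NA,NA,T1DM,12
Scalzo,SU,13,-0.3,0.9,10.1,1,NA,NA,T2DM,12
Scalzo,DPP4i,14,0.2,1.1,11.6,1.1,NA,NA,T2DM,12
Martin,DPP4i,24,-0.1,1.2,8.6,1.2,NA,NA,T2DM,24
Martin,SU,24,-0.4,1.3,8.5,1.3,NA,NA,T2DM,24
Sofer,metformin,32,-1,0.9,6.7,1.1,NA,NA,NAFLD,12
Sofer,placebo,31,0.2,1,6.3,1,NA,NA,NAFLD,12
Watanabe,TZD,13,-1,2.2,15.2,2.5,NA,NA,T2DM,24
Watanabe,SU,14,0.1,1.8,15.2,1.7,NA,NA,T2DM,24
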