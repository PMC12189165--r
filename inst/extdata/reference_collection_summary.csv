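collection,sex,variable,n,mean,sd,median,min,max
Vienna,M,age_years,30,3.8,2.6,3.3,0.1,11.0
Vienna,F,age_years,20,4.6,3.3,4.0,0.1,17.0
Graz,M,age_years,23,11.7,6.2,11.0,3.0,21.0
Graz,F,age_years,18,9.3,4.3,8.5,3.0,18.0
Terzer,M,age_years,8,2.0,3.7,0.8,0.1,11.0
Terzer,F,age_years,9,0.7,0.5,0.5,0.2,1.5
NMDID,M,age_years,45,20.8,5.3,21.0,12.0,30.0
NMDID,F,age_years,51,20.9,5.5,21.0,12.0,30.0
Vienna,M,lateral_angle_deg,30,40.3,7.1,39.9,26.7,53.3
Vienna,F,lateral_angle_deg,20,41.5,6.0,42.4,31.9,50.5
Graz,M,lateral_angle_deg,23,37.1,5.7,37.5,25.8,48.0
Graz,F,lateral_angle_deg,18,35.4,5.7,34.6,27.0,46.2
Terzer,M,lateral_angle_deg,8,45.1,9.2,48.6,29.3,56.0
Terzer,F,lateral_angle_deg,9,45.9,5.2,47.8,35.3,53.2
Vienna,M,aub_mm,30,98.2,13.0,100.0,58.9,114.1
Vienna,F,aub_mm,20,100.7,9.4,100.0,70.0,116.6
Graz,M,aub_mm,23,114.8,11.5,114.5,95.7,134.4
Graz,F,aub_mm,18,108.9,8.8,109.8,94.4,125.6
Terzer,M,aub_mm,8,79.2,14.2,76.6,62.0,110.7
Terzer,F,aub_mm,9,73.6,7.6,71.7,65.0,90.4
NMDID,M,aub_mm,45,124.5,5.4,123.6,114.3,140.3
NMDID,F,aub_mm,51,118.9,3.4,118.6,110.3,129.2
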