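"factor","level","age_bucket","gender","disease","rr_mean","rr_low","rr_high"
"demog","ALL","1","M","IHD",1,0.85,1.2
"demog","ALL","2","M","IHD",1.8,1.53,2.16
"demog","ALL","3","M","IHD",3.2,2.72,3.84
"demog","ALL","4","M","IHD",5.5,4.675,6.6
"demog","ALL","5","M","IHD",8,6.8,9.6
"demog","ALL","6","M","IHD",11,9.35,13.2
"demog","ALL","7","M","IHD",14,11.9,16.8
"demog","ALL","1","F","IHD",0.95,0.8075,1.14
"demog","ALL","2","F","IHD",1.71,1.4535,2.052
"demog","ALL","3","F","IHD",3.04,2.584,3.648
"demog","ALL","4","F","IHD",5.225,4.44125,6.27
"demog","ALL","5","F","IHD",7.6,6.46,9.12
"demog","ALL","6","F","IHD",10.45,8.8825,12.54
"demog","ALL","7","F","IHD",13.3,11.305,15.96
"demog","ALL","1","M","Diabetes",1,0.85,1.2
"demog","ALL","2","M","Diabetes",2,1.7,2.4
"demog","ALL","3","M","Diabetes",3.5,2.975,4.2
"demog","ALL","4","M","Diabetes",5,4.25,6
"demog","ALL","5","M","Diabetes",6.5,5.525,7.8
"demog","ALL","6","M","Diabetes",7.5,6.375,9
"demog","ALL","7","M","Diabetes",8.2,6.97,9.84
"demog","ALL","1","F","Diabetes",0.95,0.8075,1.14
"demog","ALL","2","F","Diabetes",1.9,1.615,2.28
"demog","ALL","3","F","Diabetes",3.325,2.82625,3.99
"demog","ALL","4","F","Diabetes",4.75,4.0375,5.7
"demog","ALL","5","F","Diabetes",6.175,5.24875,7.41
"demog","ALL","6","F","Diabetes",7.125,6.05625,8.55
"demog","ALL","7","F","Diabetes",7.79,6.6215,9.348
"smoke","ALL","1","M","IHD",3.4,2.72,4.25
"smoke","ALL","2","M","IHD",2.9,2.32,3.625
"smoke","ALL","3","M","IHD",2.4,1.92,3
"smoke","ALL","4","M","IHD",2,1.6,2.5
"smoke","ALL","5","M","IHD",1.7,1.36,2.125
"smoke","ALL","6","M","IHD",1.4,1.12,1.75
"smoke","ALL","7","M","IHD",1.2,0.96,1.5
"smoke","ALL","1","F","IHD",3.5,2.8,4.375
"smoke","ALL","2","F","IHD",3,2.4,3.75
"smoke","ALL","3","F","IHD",2.2,1.76,2.75
"smoke","ALL","4","F","IHD",1.6,1.28,2
"smoke","ALL","5","F","IHD",1.3,1.04,1.625
"smoke","ALL","6","F","IHD",1.2,0.96,1.5
"smoke","ALL","7","F","IHD",1.15,0.92,1.4375
"smoke","ALL","ALL","ALL","Diabetes",1.6,1.35,1.9
"secsmoke","ALL","ALL","ALL","IHD",1.25,1.1,1.45
"secsmoke","ALL","ALL","ALL","Diabetes",1.12,1.02,1.25
"phys","2","1","ALL","IHD",0.86,0.731,0.946
"phys","2","2","ALL","IHD",0.84,0.714,0.924
"phys","2","3","ALL","IHD",0.82,0.697,0.902
"phys","2","4","ALL","IHD",0.8,0.68,0.88
"phys","2","5","ALL","IHD",0.78,0.663,0.858
"phys","2","6","ALL","IHD",0.76,0.646,0.836
"phys","2","7","ALL","IHD",0.74,0.629,0.814
"phys","3","1","ALL","IHD",0.74,0.629,0.814
"phys","3","2","ALL","IHD",0.72,0.612,0.792
"phys","3","3","ALL","IHD",0.7,0.595,0.77
"phys","3","4","ALL","IHD",0.68,0.578,0.748
"phys","3","5","ALL","IHD",0.66,0.561,0.726
"phys","3","6","ALL","IHD",0.64,0.544,0.704
"phys","3","7","ALL","IHD",0.62,0.527,0.682
"phys","4","1","ALL","IHD",0.62,0.527,0.682
"phys","4","2","ALL","IHD",0.6,0.51,0.66
"phys","4","3","ALL","IHD",0.58,0.493,0.638
"phys","4","4","ALL","IHD",0.56,0.476,0.616
"phys","4","5","ALL","IHD",0.54,0.459,0.594
"phys","4","6","ALL","IHD",0.52,0.442,0.572
"phys","4","7","ALL","IHD",0.5,0.425,0.55
"phys","2","ALL","ALL","Diabetes",0.85,0.7225,0.935
"phys","3","ALL","ALL","Diabetes",0.72,0.612,0.792
"phys","4","ALL","ALL","Diabetes",0.61,0.5185,0.671
"bmi","ALL","1","ALL","IHD",2.2,1.87,2.64
"bmi","ALL","2","ALL","IHD",2,1.7,2.4
"bmi","ALL","3","ALL","IHD",1.8,1.53,2.16
"bmi","ALL","4","ALL","IHD",1.65,1.4025,1.98
"bmi","ALL","5","ALL","IHD",1.5,1.275,1.8
"bmi","ALL","6","ALL","IHD",1.35,1.1475,1.62
"bmi","ALL","7","ALL","IHD",1.25,1.0625,1.5
"bmi","ALL","1","ALL","Diabetes",2.5,2.125,3
"bmi","ALL","2","ALL","Diabetes",2.3,1.955,2.76
"bmi","ALL","3","ALL","Diabetes",2.1,1.785,2.52
"bmi","ALL","4","ALL","Diabetes",1.9,1.615,2.28
"bmi","ALL","5","ALL","Diabetes",1.7,1.445,2.04
"bmi","ALL","6","ALL","Diabetes",1.5,1.275,1.8
"bmi","ALL","7","ALL","Diabetes",1.35,1.1475,1.62
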