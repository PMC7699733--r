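sample_id,cancer_status,gender,smoking,batch,stage,vital_status,age_group
C01,NO,F,current,1,no,alive,<55
C02,NO,F,current,1,no,alive,<55
C03,NO,F,current,2,no,alive,<55
C04,NO,F,current,2,no,alive,<55
C05,NO,F,former,2,no,alive,>55
C06,NO,F,former,2,no,alive,NA
C07,NO,F,non,2,no,alive,NA
C08,NO,F,non,2,no,alive,NA
C09,NO,M,unknown,2,no,alive,NA
C10,NO,M,unknown,2,no,alive,NA
C11,NO,M,unknown,2,no,alive,NA
C12,NO,M,unknown,3,NA,alive,NA
P01,YES,F,current,1,4,dead,<55
P02,YES,F,current,1,4,dead,>55
P03,YES,F,current,1,4,dead,NA
P04,YES,M,former,1,4,dead,NA
P05,YES,M,former,1,4,dead,NA
P06,YES,M,former,2,2,alive,NA
P07,YES,M,former,2,3,alive,NA
P08,YES,M,former,2,NA,alive,NA
P09,YES,M,former,2,NA,alive,NA
P10,YES,M,non,2,NA,alive,NA
P11,YES,M,unknown,2,NA,alive,NA
P12,YES,NA,unknown,3,NA,alive,NA
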