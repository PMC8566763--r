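participant,age,gender,eye_tested,md_tested,md_covered,ivf_score
P003,70,male,left,-6.65,-26.26,14
P004,73,male,right,-19.84,-10.28,21
P008,64,male,left,-1.42,-15.31,0
P009,66,female,right,-4.86,-9.85,4
P010,69,female,right,-17.24,-6.96,10
P013,41,male,right,-28.98,-28.96,88
P014,72,female,left,-32.76,-23.74,79
P016,69,male,left,-16.45,-24.48,77
P021,78,male,right,-6,0.61,0
P022,65,female,left,-3.34,-1.56,0
P023,47,female,left,-5.24,-5.29,0
P025,78,male,left,-5.81,-20.23,12
P026,81,male,right,-24.9,-2.78,7
P027,67,male,left,-23.58,-16.76,37
P028,60,male,left,-24.49,-24.07,72
P029,64,male,right,NA,NA,NA
P030,77,male,left,-17.99,-15.75,65
P031,63,female,right,-8.68,-0.93,3
P032,68,female,right,-6.21,-5.82,2
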