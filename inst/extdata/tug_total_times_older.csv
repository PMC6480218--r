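# Paired total 3-m TUG times for the older-adult validation group (n = 12),
# with risk-of-falling category labels (no / low / high) assigned from each
# method's total time following the Chilean Ministry of Health manual.
# Subject 12's video time was reported without decimals (43 s).
subject,height_cm,weight_kg,age_yr,sex,video_time_s,imu_time_s,video_rof,imu_rof
1,168,75,60,male,11.00,10.51,low,low
2,168,72,60,male,9.63,8.98,no,no
3,156,90,63,male,10.73,10.57,low,low
4,170,68,65,male,9.76,9.59,no,no
5,179,64,71,male,12.00,11.95,low,low
6,157,62,60,female,13.76,13.13,low,low
7,178,93,67,male,9.36,9.27,no,no
8,160,51,63,female,9.03,8.87,no,no
9,145,70,59,female,10.43,9.92,low,no
10,173,84,59,male,10.60,10.23,low,low
11,160,68,59,female,9.33,9.44,low,low
12,157,61,93,female,43.00,42.99,high,high
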