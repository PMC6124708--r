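id,sex,age,bmi,neck_cm,sys_bp,dia_bp,ess,hypertension,snoring,tiredness,observed_apnea,ahi
syn000001,male,63,35.3,39.6,124.3,86.6,10,no,no,yes,no,46.9
syn000002,male,51.3,41.6,46.1,131,99.5,17,yes,yes,yes,no,81.8
syn000003,female,45.9,41.8,38.9,104.9,79.7,10,no,yes,no,yes,74.1
syn000004,male,64.9,35.7,44.3,128.3,92.6,10,yes,yes,yes,yes,117.7
syn000005,male,64.3,43.1,47,143.1,97.9,8,yes,yes,no,no,16.6
syn000006,male,66.5,41.7,49,166.6,117.4,10,yes,yes,yes,no,34.4
syn000007,male,41,21.2,39.4,130.4,100.9,9,yes,yes,yes,yes,40
syn000008,male,46.6,29.8,46,124.8,90,18,no,no,yes,no,26.8
syn000009,female,46.9,22.7,36.5,144.3,85.2,23,yes,no,yes,no,18.7
syn000010,male,40,42.7,48.1,141.6,97.5,22,yes,yes,no,yes,94.6
syn000011,male,69.6,22.7,45.7,147,101.8,10,yes,yes,yes,no,12.9
syn000012,male,61.7,31.8,39.8,92.9,65.7,12,no,yes,no,no,15.4
syn000013,female,39.3,36.2,37.8,177.3,127.6,2,yes,yes,no,yes,52.3
syn000014,female,64.1,43.9,45.6,117.1,84.6,20,no,yes,yes,yes,16
syn000015,male,51.3,32,43,152.7,113,13,yes,yes,yes,no,44.5
syn000016,male,74.6,39.8,44.3,151.5,99.6,24,yes,yes,yes,no,66.7
syn000017,female,51.6,37.9,48.6,134.3,100.2,9,yes,yes,no,yes,57
syn000018,male,46.5,43.4,53.9,146.1,99,15,yes,yes,no,yes,135.7
syn000019,male,74.4,28.6,41.7,131.1,91.3,16,yes,yes,yes,yes,36.9
syn000020,female,75.4,31.7,35.5,105.4,65.6,8,no,yes,no,no,68
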