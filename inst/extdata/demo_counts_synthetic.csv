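sample,replicate,channel,positives,total
patient_1,1,A,1338,20000
patient_1,1,B,4765,20000
patient_1,2,A,1326,20000
patient_1,2,B,4850,20000
patient_1,3,A,1347,20000
patient_1,3,B,4801,20000
patient_2,1,A,1337,20000
patient_2,1,B,923,20000
patient_2,2,A,1483,20000
patient_2,2,B,989,20000
patient_2,3,A,1381,20000
patient_2,3,B,953,20000
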