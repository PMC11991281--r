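parameter,farming_method,Number,Min,Mean,Max,StDev,CV_printed
LAI,CFM,499,0.500,4.878,10.370,1.704,0.349
LAI,AFM,377,0.130,4.058,9.810,2.035,0.501
PRI,CFM,503,-0.0371,0.0228,0.0766,0.0196,0.860
PRI,AFM,378,-0.0770,0.0201,0.0596,0.0251,1.249
PhiPSII,CFM,477,0.0729,0.4121,0.8277,0.1671,0.405
PhiPSII,AFM,350,0.0819,0.4586,0.8648,0.1717,0.374
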