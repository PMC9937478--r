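table,disease,service,sex,value_thousand_usd
services,NA,hospitalization,NA,8019
services,NA,consultation,NA,4905
services,NA,medication,NA,2198
by_disease,CHD,hospitalization,NA,3108
by_disease,CHD,consultation,NA,2261
by_disease,CHD,medication,NA,221
by_disease,stroke,hospitalization,NA,2433
by_disease,stroke,consultation,NA,1310
by_disease,hypertensive,hospitalization,NA,1528
by_disease,hypertensive,consultation,NA,823
by_disease,hypertensive,medication,NA,1977
by_disease,RHD,hospitalization,NA,951
by_disease,RHD,consultation,NA,512
hospitalization,CHD,NA,male,1702
hospitalization,CHD,NA,female,1406
hospitalization,stroke,NA,male,1126
hospitalization,stroke,NA,female,1306
hospitalization,hypertensive,NA,male,585
hospitalization,hypertensive,NA,female,943
hospitalization,RHD,NA,male,453
hospitalization,RHD,NA,female,498
consultation,CHD,NA,male,1479
consultation,CHD,NA,female,782
consultation,stroke,NA,male,606
consultation,stroke,NA,female,703
consultation,hypertensive,NA,male,315
consultation,hypertensive,NA,female,507
consultation,RHD,NA,male,244
consultation,RHD,NA,female,268
medication,CHD,NA,male,141
medication,CHD,NA,female,79
medication,hypertensive,NA,male,727
medication,hypertensive,NA,female,1250
productivity,CHD,NA,male,1932
productivity,CHD,NA,female,2141
productivity,stroke,NA,male,1408
productivity,stroke,NA,female,1349
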