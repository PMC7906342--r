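strategy,field,value
none,screening_tests,0
none,biopsies,2789
none,negative_biopsies,1302
none,diagnosed,1487
none,screen_detected,0
none,overdiagnosed,0
none,pc_deaths,502
none,life_years,794308
none,qalys,694959
none,cost_screening,0
none,cost_diagnosis,155
none,cost_treatment,721
none,cost_advanced_disease,2153
none,cost_direct,3029
none,cost_productivity,91
none,cost_societal,3120
psa,screening_tests,35804
psa,biopsies,7947
psa,negative_biopsies,6339
psa,diagnosed,1608
psa,screen_detected,534
psa,overdiagnosed,121
psa,pc_deaths,430
psa,life_years,794960
psa,qalys,695325
psa,cost_screening,214
psa,cost_diagnosis,445
psa,cost_treatment,1015
psa,cost_advanced_disease,1847
psa,cost_direct,3521
psa,cost_productivity,168
psa,cost_societal,3689
s3m_1,screening_tests,34943
s3m_1,biopsies,5903
s3m_1,negative_biopsies,4307
s3m_1,diagnosed,1596
s3m_1,screen_detected,509
s3m_1,overdiagnosed,109
s3m_1,pc_deaths,433
s3m_1,life_years,794943
s3m_1,qalys,695330
s3m_1,cost_screening,518
s3m_1,cost_diagnosis,338
s3m_1,cost_treatment,996
s3m_1,cost_advanced_disease,1857
s3m_1,cost_direct,3708
s3m_1,cost_productivity,164
s3m_1,cost_societal,3872
s3m_1.5,screening_tests,34864
s3m_1.5,biopsies,5711
s3m_1.5,negative_biopsies,4119
s3m_1.5,diagnosed,1593
s3m_1.5,screen_detected,503
s3m_1.5,overdiagnosed,106
s3m_1.5,pc_deaths,433
s3m_1.5,life_years,794939
s3m_1.5,qalys,695329
s3m_1.5,cost_screening,429
s3m_1.5,cost_diagnosis,327
s3m_1.5,cost_treatment,991
s3m_1.5,cost_advanced_disease,1860
s3m_1.5,cost_direct,3607
s3m_1.5,cost_productivity,163
s3m_1.5,cost_societal,3770
s3m_2,screening_tests,34792
s3m_2,biopsies,5525
s3m_2,negative_biopsies,3937
s3m_2,diagnosed,1588
s3m_2,screen_detected,494
s3m_2,overdiagnosed,102
s3m_2,pc_deaths,434
s3m_2,life_years,794930
s3m_2,qalys,695327
s3m_2,cost_screening,378
s3m_2,cost_diagnosis,316
s3m_2,cost_treatment,984
s3m_2,cost_advanced_disease,1865
s3m_2,cost_direct,3542
s3m_2,cost_productivity,161
s3m_2,cost_societal,3703
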