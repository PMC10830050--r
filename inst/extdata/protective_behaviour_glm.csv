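source,ss,df
Corrected Model,2881.152,14
Intercept,1462.938,1
Segments,1751.359,6
Gender,94.174,1
Dummy_Ethnicity,5.820,4
EducationSelf,27.807,1
Income,72.367,1
Age,153.335,1
Error,10340.288,4841
Total,68737.000,4856
Corrected Total,13221.440,4855
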