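enzyme,gene,substrate,km_uM,kcat_per_s,stoichiometry,kcat_assumed
FDS1,FDS,IDP,29.4,0.7,1,FALSE
FDS1,FDS,GDP,17.2,NA,1,FALSE
ADS,ADS,FDP,2,0.004,1,FALSE
DBR2,DBR2,AA,19,2.6,1,FALSE
ALDH1,ALDH1,DHAA,8.8,7.7,1,FALSE
ALDH1,ALDH1,AA,2.6,1.5,1,FALSE
RED1,RED1,DHAA,67,0.28,1,FALSE
SQS,SQS,FDP,NA,1,2,TRUE
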