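gene,efficiency
actin,1.91
ADS,1.88
ALDH1,1.82
CPR,1.90
CPS,1.85
CYP71AV1,1.83
DBR2,1.91
DBR2_OPR3,1.84
DXR,1.92
DXS,1.92
ECS,1.86
FDS,1.93
GAS,1.83
HDR,1.86
HMGR,1.83
PAL,1.87
RED1,1.92
SQS,1.82
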