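herbicide,ic_duration_h,source,protection_pct,etv_ugL,printed_protective
diuron,24,ANZECC_current,99,1.8,FALSE
diuron,24,ANZECC_current,95,1.8,FALSE
diuron,24,ANZECC_current,90,1.8,FALSE
diuron,24,ANZECC_proposed,99,0.08,TRUE
diuron,24,ANZECC_proposed,95,0.3,TRUE
diuron,24,ANZECC_proposed,90,0.4,TRUE
diuron,24,GBRMPA,99,0.9,TRUE
diuron,24,GBRMPA,95,1.6,FALSE
diuron,24,GBRMPA,90,2.3,FALSE
fluometuron,24,ANZECC_current,99,NA,NA
fluometuron,24,ANZECC_current,95,NA,NA
fluometuron,24,ANZECC_current,90,NA,NA
fluometuron,24,ANZECC_proposed,99,NA,NA
fluometuron,24,ANZECC_proposed,95,NA,NA
fluometuron,24,ANZECC_proposed,90,NA,NA
fluometuron,24,GBRMPA,99,NA,NA
fluometuron,24,GBRMPA,95,NA,NA
fluometuron,24,GBRMPA,90,NA,NA
tebuthiuron,24,ANZECC_current,99,0.02,TRUE
tebuthiuron,24,ANZECC_current,95,2.2,TRUE
tebuthiuron,24,ANZECC_current,90,20,FALSE
tebuthiuron,24,ANZECC_proposed,99,4.3,FALSE
tebuthiuron,24,ANZECC_proposed,95,8.8,FALSE
tebuthiuron,24,ANZECC_proposed,90,12.0,FALSE
tebuthiuron,24,GBRMPA,99,0.02,TRUE
tebuthiuron,24,GBRMPA,95,2,TRUE
tebuthiuron,24,GBRMPA,90,20,TRUE
atrazine,24,ANZECC_current,99,0.7,TRUE
atrazine,24,ANZECC_current,95,13,FALSE
atrazine,24,ANZECC_current,90,45,FALSE
atrazine,24,ANZECC_proposed,99,2.8,TRUE
atrazine,24,ANZECC_proposed,95,3.8,FALSE
atrazine,24,ANZECC_proposed,90,4.6,FALSE
atrazine,24,GBRMPA,99,0.6,TRUE
atrazine,24,GBRMPA,95,1.4,TRUE
atrazine,24,GBRMPA,90,2.5,TRUE
ametryn,48,ANZECC_current,99,NA,NA
ametryn,48,ANZECC_current,95,NA,NA
ametryn,48,ANZECC_current,90,NA,NA
ametryn,48,ANZECC_proposed,99,0.02,TRUE
ametryn,48,ANZECC_proposed,95,0.1,TRUE
ametryn,48,ANZECC_proposed,90,0.3,TRUE
ametryn,48,GBRMPA,99,0.5,TRUE
ametryn,48,GBRMPA,95,1.0,FALSE
ametryn,48,GBRMPA,90,1.6,FALSE
metribuzin,48,ANZECC_current,99,NA,NA
metribuzin,48,ANZECC_current,95,NA,NA
metribuzin,48,ANZECC_current,90,NA,NA
metribuzin,48,ANZECC_proposed,99,NA,NA
metribuzin,48,ANZECC_proposed,95,NA,NA
metribuzin,48,ANZECC_proposed,90,NA,NA
metribuzin,48,GBRMPA,99,NA,NA
metribuzin,48,GBRMPA,95,NA,NA
metribuzin,48,GBRMPA,90,NA,NA
simazine,24,ANZECC_current,99,NA,NA
simazine,24,ANZECC_current,95,NA,NA
simazine,24,ANZECC_current,90,NA,NA
simazine,24,ANZECC_proposed,99,NA,NA
simazine,24,ANZECC_proposed,95,NA,NA
simazine,24,ANZECC_proposed,90,NA,NA
simazine,24,GBRMPA,99,0.2,TRUE
simazine,24,GBRMPA,95,3.2,TRUE
simazine,24,GBRMPA,90,11,TRUE
prometryn,48,ANZECC_current,99,NA,NA
prometryn,48,ANZECC_current,95,NA,NA
prometryn,48,ANZECC_current,90,NA,NA
prometryn,48,ANZECC_proposed,99,NA,NA
prometryn,48,ANZECC_proposed,95,NA,NA
prometryn,48,ANZECC_proposed,90,NA,NA
prometryn,48,GBRMPA,99,NA,NA
prometryn,48,GBRMPA,95,NA,NA
prometryn,48,GBRMPA,90,NA,NA
bromacil,24,ANZECC_current,99,NA,NA
bromacil,24,ANZECC_current,95,NA,NA
bromacil,24,ANZECC_current,90,NA,NA
bromacil,24,ANZECC_proposed,99,NA,NA
bromacil,24,ANZECC_proposed,95,NA,NA
bromacil,24,ANZECC_proposed,90,NA,NA
bromacil,24,GBRMPA,99,NA,NA
bromacil,24,GBRMPA,95,NA,NA
bromacil,24,GBRMPA,90,NA,NA
hexazinone,48,ANZECC_current,99,75,FALSE
hexazinone,48,ANZECC_current,95,75,FALSE
hexazinone,48,ANZECC_current,90,75,FALSE
hexazinone,48,ANZECC_proposed,99,0.9,TRUE
hexazinone,48,ANZECC_proposed,95,1.2,TRUE
hexazinone,48,ANZECC_proposed,90,1.5,TRUE
hexazinone,48,GBRMPA,99,1.2,TRUE
hexazinone,48,GBRMPA,95,1.2,TRUE
hexazinone,48,GBRMPA,90,1.2,TRUE
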