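herbicide,duration,test_phylum,common_name,endpoint,response_concentration_ugL,source
diuron,24 h,Angiospermae,seagrass,dF/Fm' IC50,4.3,this assay
diuron,24 h,Angiospermae,seagrass,dF/Fm' IC50,3.5,literature
diuron,72 h,Angiospermae,seagrass,dF/Fm'/FvFm,2.4-2.47,literature
diuron,5 day,Angiospermae,seagrass,dF/Fm' LOEC,0.1,literature
diuron,4 days,Angiospermae,seagrass,dF/Fm' LOEC,10,literature
diuron,77 days,Angiospermae,seagrass,dF/Fm' IC50,2.4-2.8,literature
diuron,34 h,Dinoflagellate,coral,dF/Fm' IC50,2.9-5.9,literature
diuron,2-3 mo,Dinoflagellate,coral,dF/Fm' IC50,1.2-5.0,literature
diuron,4 day,Heterokontophyceae,diatom,dF/Fm' IC50,2.6-18,literature
diuron,4 day,Chlorophyceae,green algae,dF/Fm' IC50,2.1,literature
fluometuron,24 h,Angiospermae,seagrass,dF/Fm' IC50,132,this assay
fluometuron,30 min + 48 h,Chlorophyceae,green algae,growth,2.5-10 ml/L,literature
tebuthiuron,24 h,Angiospermae,seagrass,dF/Fm' IC50,28,this assay
tebuthiuron,72 h,Angiospermae,seagrass,dF/Fm' IC50,29.1-29.7,literature
tebuthiuron,24 h,Dinoflagellate,coral,dF/Fm' IC50,175,literature
tebuthiuron,4 day,Heterokontophyceae,diatom,dF/Fm' IC50,51-94,literature
tebuthiuron,4 day,Chlorophyceae,green algae,dF/Fm' IC50,12,literature
atrazine,24 h,Angiospermae,seagrass,dF/Fm' IC50,22,this assay
atrazine,72 h,Angiospermae,seagrass,dF/Fm' IC50,13.4-18.2,literature
atrazine,96 h,Angiospermae,seagrass,dF/Fm' LOEC,10,literature
atrazine,14 d,Angiospermae,aquatic plants,dF/Fm' IC50,22-132,literature
atrazine,96 h,Chlorophyceae,green algae,dF/Fm' IC50,94-176,literature
atrazine,24 h,Chlorophyceae,green algae,dF/Fm' IC50,38.8,literature
atrazine,2 h,Chlorophyceae,green algae,dF/Fm' IC50,103,literature
atrazine,2 h,Heterokontophyceae,diatom,dF/Fm' IC50,45,literature
atrazine,24 h,Dinoflagellate,coral,dF/Fm' IC50,45,literature
atrazine,34 h,Dinoflagellate,coral,dF/Fm' IC50,37-88.2,literature
atrazine,4 day,Heterokontophyceae,diatom,dF/Fm' IC50,34-77,literature
atrazine,4 day,Chlorophyceae,green algae,dF/Fm' IC50,14,literature
ametryn,48 h,Angiospermae,seagrass,dF/Fm' IC50,3.6,this assay
ametryn,24 h,Chlorophyceae,green algae,dF/Fm' IC50,3.6,literature
ametryn,24 h,Dinoflagellate,coral,dF/Fm' IC50,1.7,literature
metribuzin,48 h,Angiospermae,seagrass,dF/Fm' IC50,4.8,this assay
metribuzin,14 d,Angiospermae,aquatic plants,dF/Fm' IC50,14-36,literature
metribuzin,h - days,Chlorophyceae,green algae,dF/Fm' IC50,12.3-39.7,literature
metribuzin,96 h,Chlorophyceae,green algae,dF/Fm' IC50,23-152,literature
simazine,24 h,Angiospermae,seagrass,dF/Fm' IC50,28,this assay
simazine,96 h,Angiospermae,seagrass,dF/Fm' LOEC,10,literature
simazine,24 h,Chlorophyceae,green algae,dF/Fm' IC50,56.9,literature
simazine,24 h,Dinoflagellate,coral,dF/Fm' IC50,150,literature
simazine,2 h,Chlorophyceae,green algae,dF/Fm' IC50,76,literature
simazine,2 h,Heterokontophyceae,diatom,dF/Fm' IC50,400,literature
prometryn,48 h,Angiospermae,seagrass,dF/Fm' IC50,6.7,this assay
prometryn,24 h,Chlorophyceae,green algae,dF/Fm'/FvFm,13.2,literature
bromacil,24 h,Angiospermae,seagrass,dF/Fm' IC50,25,this assay
bromacil,2 h,Phaeophyceae,macroalgae,dF/Fm' IC50,8.23,literature
hexazinone,48 h,Angiospermae,seagrass,dF/Fm' IC50,11,this assay
hexazinone,72 h,Angiospermae,seagrass,dF/Fm'/FvFm,4.4-6.9,literature
hexazinone,24 h,Dinoflagellate,coral,dF/Fm'/FvFm,8.8,literature
hexazinone,2 h,Chlorophyceae,green algae,dF/Fm'/FvFm,21,literature
hexazinone,2 h,Heterokontophyceae,diatom,dF/Fm' IC50,22,literature
hexazinone,4 day,Heterokontophyceae,diatom,dF/Fm' IC50,5.7-6.9,literature
hexazinone,4 day,Chlorophyceae,green algae,dF/Fm' IC50,2.4,literature
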