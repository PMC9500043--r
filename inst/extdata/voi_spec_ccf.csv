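name,abbreviation,laterality,acronyms
Anterior cingulate area,ACA,bilateral,ACA
Auditory areas,AUD,bilateral,AUD
Cerebellum,CB,central,CB
Hindbrain,HB,central,P;MY
Hippocampal region,HIP,bilateral,HIP
Hypothalamus,HY,bilateral,HY
Midbrain,MB,central,MB
Olfactory areas,OLF,bilateral,OLF
Orbital areas,ORB,bilateral,ORB
Somatomotor areas,MO,bilateral,MO
Somatosensory areas,SS,bilateral,SS
Striatum dorsal,STRd,bilateral,STRd
Striatum ventral,STRv,bilateral,STRv
Thalamus,TH,bilateral,TH
Visual areas,VIS,bilateral,VIS
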