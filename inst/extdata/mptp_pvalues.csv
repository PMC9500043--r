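template,area,p_value
ccf,Anterior cingulate area left,0.0068
ccf,Anterior cingulate area right,0.0039
ccf,Auditory cortex left,0.5459
ccf,Auditory cortex right,0.4974
ccf,Striatum dorsal left,0.0007
ccf,Striatum dorsal right,0.0006
ccf,Striatum ventral left,0.7122
ccf,Striatum ventral right,0.9702
ccf,Cerebellum,0.9875
ccf,Hindbrain,0.4002
ccf,Hippocampal region left,0.1113
ccf,Hippocampal region right,0.0801
ccf,Hypothalamus left,0.2758
ccf,Hypothalamus right,0.7514
ccf,Olfactory areas left,0.7972
ccf,Olfactory areas right,0.6618
ccf,Orbital areas left,0.0311
ccf,Orbital areas right,0.0055
ccf,Somatomotor areas left,0.0634
ccf,Somatomotor areas right,0.0392
ccf,Somatosensory areas left,0.6806
ccf,Somatosensory areas right,0.0271
ccf,Thalamus left,0.0003
ccf,Thalamus right,0.0242
ccf,Visual areas left,0.8395
ccf,Visual areas right,0.0889
ccf,Midbrain,0.0436
mm,Amygdala R,0.7648
mm,Amygdala L,0.6727
mm,Cortex,0.0730
mm,Striatum R,0.0003
mm,Striatum L,0.0002
mm,Cerebellum,0.9992
mm,Basal forebrain septum,0.1229
mm,Hippocampus L,0.3103
mm,Hippocampus R,0.5574
mm,Hypothalamus,0.5217
mm,Olfactory bulb,0.2139
mm,Superior colliculi,0.1677
mm,Inferior colliculi R,0.8842
mm,Inferior colliculi L,0.5472
mm,Brain stem,0.9439
mm,Thalamus,0.0040
mm,Central gray,0.0148
mm,Midbrain R,0.3966
mm,Midbrain L,0.4016
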