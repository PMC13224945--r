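term	modality
in vitro	in vitro
patch clamp	in vitro
electrophysiolog	in vitro
elisa	in vitro
immunoassay	in vitro
western blot	in vitro
cell culture	in vitro
cardiomyocyte culture	in vitro
fluorescence	in vitro
spectrophotometr	in vitro
flow cytometry	in vitro
qpcr	in vitro
microelectrode array	in vitro
in vivo	in vivo
echocardiograph	in vivo
electrocardiogram	in vivo
telemetry	in vivo
histopatholog	in vivo
blood pressure	in vivo
plasma concentration	in vivo
serum biomarker	in vivo
necropsy	in vivo
in silico	in silico
simulation	in silico
computational model	in silico
qsar	in silico
molecular docking	in silico
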