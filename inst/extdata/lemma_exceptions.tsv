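word	lemma
matrices	matrix
analyses	analysis
criteria	criterion
phenomena	phenomenon
bacteria	bacterium
mitochondria	mitochondrion
nuclei	nucleus
stimuli	stimulus
loci	locus
fungi	fungus
mice	mouse
men	man
women	woman
children	child
feet	foot
teeth	tooth
axes	axis
bases	base
crises	crisis
hypotheses	hypothesis
metastases	metastasis
syntheses	synthesis
apoptoses	apoptosis
viruses	virus
buses	bus
species	species
series	series
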