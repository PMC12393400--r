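neuron	class	category	region	loci
AFDL	AFD	sensory	head	unc-17;eat-4
AFDR	AFD	sensory	head	unc-17;eat-4
M5	M5	motor	pharynx	unc-17;eat-4
DVA	DVA	interneuron	tail	unc-17;eat-4
PVN	PVN	interneuron	tail	unc-17;eat-4
I2L	I2	interneuron	pharynx	unc-47;eat-4
PDE	PDE	sensory	midbody	dat-1;eat-4
M4	M4	motor	pharynx	unc-47;unc-17
SDQR	SDQ	interneuron	midbody	unc-47;unc-17
SMD	SMD	motor	head	unc-47;unc-17
ADF	ADF	sensory	head	tph-1;unc-17
HSN	HSN	motor	midbody	tph-1;unc-17
VC4	VC	motor	midbody	tph-1;unc-17
VC5	VC	motor	midbody	tph-1;unc-17
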