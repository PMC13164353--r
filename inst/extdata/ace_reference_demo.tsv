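# Curated demonstration stand-in for a bioactive-peptide database:
# short peptides with reported ACE inhibitory (and a few other) activities.
# Not the BIOPEP-UWM database; shipped for examples and tests only.
activity	sequence
ACE inhibitor	IY
ACE inhibitor	VY
ACE inhibitor	KF
ACE inhibitor	IW
ACE inhibitor	VW
ACE inhibitor	LW
ACE inhibitor	AW
ACE inhibitor	GY
ACE inhibitor	RY
ACE inhibitor	HY
ACE inhibitor	AY
ACE inhibitor	FY
ACE inhibitor	VF
ACE inhibitor	IF
ACE inhibitor	YP
ACE inhibitor	KP
ACE inhibitor	AP
ACE inhibitor	GP
ACE inhibitor	RP
ACE inhibitor	IPP
ACE inhibitor	VPP
ACE inhibitor	LKP
ACE inhibitor	IKP
ACE inhibitor	IKW
ACE inhibitor	LRP
ACE inhibitor	FQP
ACE inhibitor	AVP
ACE inhibitor	GKP
ACE inhibitor	VAP
ACE inhibitor	HHL
DPP-IV inhibitor	GP
DPP-IV inhibitor	PP
DPP-IV inhibitor	IP
DPP-IV inhibitor	VP
DPP-IV inhibitor	WV
DPP-IV inhibitor	IPI
DPP-IV inhibitor	VPL
antioxidant	YG
antioxidant	HH
antioxidant	LH
antioxidant	YGG
antioxidant	PHH
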