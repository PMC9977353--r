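SYNTH_ACUTE_PHASE	synthetic example set	PROT001	PROT004	PROT007	PROT012	PROT019	PROT023
SYNTH_COMPLEMENT	synthetic example set	PROT002	PROT005	PROT011	PROT020	PROT031	PROT042	PROT055
SYNTH_COAGULATION	synthetic example set	PROT003	PROT013	PROT021	PROT034	PROT048
SYNTH_IMMUNOGLOBULIN	synthetic example set	PROT006	PROT014	PROT027	PROT038	PROT044	PROT052	PROT058
SYNTH_LIPID_TRANSPORT	synthetic example set	PROT008	PROT016	PROT025	PROT036	PROT050
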