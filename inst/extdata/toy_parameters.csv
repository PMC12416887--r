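residue,atom,charge_e,radius_A
ARG,CZ,0.64,2.0
ARG,CA,0.07,2.275
ASP,CG,0.62,2.0
GLU,CD,0.62,2.0
HOH,O,-0.834,1.768
POT,K,1.0,1.764
ION,Q,1.0,2.0
*,CA,0.07,2.275
*,O,-0.51,1.7
*,N,-0.47,1.85
*,C,0.51,2.0
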