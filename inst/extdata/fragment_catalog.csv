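# glntrace fragment catalog v1
# GC-MS SIM fragments of TBDMS (MtBSTFA) / ethoxime derivatives, [M-57]+
# (t-butyl loss). Elemental compositions derived from the derivatization
# chemistry; m0_mz is the monitored nominal M0 channel.
metabolite,backbone_carbons,C,H,N,O,Si,S,m0_mz
lactate,3,11,25,0,3,2,0,261.2
fumarate,4,12,23,0,4,2,0,287.1
succinate,4,12,25,0,4,2,0,289.1
alpha_ketoglutarate,5,15,30,1,5,2,0,360.2
malate,4,18,39,0,5,3,0,419.3
aspartate,4,18,40,1,4,3,0,418.2
glutamate,5,19,42,1,4,3,0,432.2
two_hydroxyglutarate,5,19,41,0,5,3,0,433.2
citrate,6,26,55,0,7,4,0,591.4
glutamine,5,19,43,2,3,3,0,431.2
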