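duplex_id	sense_notation	antisense_notation	provenance
parent	AfscsGfuUfaGfcAfuCfgAfaUfgCfuAfgAf-L96	usCfsuAfgCfaUfuCfgauGfcUfaAfcGfususu	figure-derived, not ground truth; synthetic placeholder bases
dv5	AfscsGfuUfaGfcAfuCfgAfaUfgCfuAfgAf-L96	usCfsuagCfauUfcgauGfcUfaacgususu	figure-derived, not ground truth; synthetic placeholder bases
dv6	AfscsGfuUfaGfcAfuCfgAfaUfgCfuAfgAf-L96	usCfsuagCfauucgauGfcUfaacgususu	figure-derived, not ground truth; synthetic placeholder bases
dv7	AfscsGfuUfaGfcAfuCfgAfaUfgCfuAfgAf-L96	usCfsuagCfaUfUfcgauGfcUfaacgususu	figure-derived, not ground truth; synthetic placeholder bases
dv18	ascsguuAfgcAfuCfgAfaugcuaga-L96	usCfsuagCfaUfUfcgauGfcUfaacgususu	figure-derived, not ground truth; synthetic placeholder bases
dv22	ascsguuAfgcAfuCfgAfaugcuaga-L96	usCfsuagCfauucgauGfcUfaacgususu	figure-derived, not ground truth; synthetic placeholder bases
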