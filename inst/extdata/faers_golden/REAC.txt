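caseid$caseversion$pt
R001$1$DEEP VEIN THROMBOSIS
R001$1$NAUSEA
R002$1$MELAENA
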