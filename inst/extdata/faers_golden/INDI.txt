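caseid$caseversion$indi_pt
R001$1$Glioblastoma multiforme
R002$1$Anaplastic astrocytoma
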