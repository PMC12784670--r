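caseid$caseversion$sex$age$wt$occp_cod
R001$1$M$$$
R002$1$$$$
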