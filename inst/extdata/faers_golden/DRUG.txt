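caseid$caseversion$drugname$prod_ai$role_cod
R001$1$Avastin$AVASTIN$PS
R001$1$TEMOZOLOMIDE$TEMOZOLOMIDE$C
R002$1$Gliadel$GLIADEL$SS
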