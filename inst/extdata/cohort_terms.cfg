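# Glioma cohort definitions: one block per definition, one search term per
# line. Matching is case-insensitive contiguous substring over the selected
# free-text fields (indications and history/diagnosis text).
[broad]
GLIOMA
MALIGNANT GLIOMA
GLIOBLASTOMA
GLIOBLASTOMA MULTIFORME
ASTROCYTOMA
ANAPLASTIC ASTROCYTOMA
OLIGODENDROGLIOMA
ANAPLASTIC OLIGODENDROGLIOMA
[strict]
MALIGNANT GLIOMA
GLIOBLASTOMA
GLIOBLASTOMA MULTIFORME
ANAPLASTIC ASTROCYTOMA
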