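# Composite endpoint definitions: one block per endpoint, one MedDRA
# preferred term per line. A report counts once toward an endpoint if it
# lists at least one of the endpoint's PTs, however many match.
[VTE]
DEEP VEIN THROMBOSIS
PULMONARY EMBOLISM
VENOUS THROMBOSIS
EMBOLISM VENOUS
VENOUS THROMBOSIS LIMB
PELVIC VENOUS THROMBOSIS
JUGULAR VEIN THROMBOSIS
SUBCLAVIAN VEIN THROMBOSIS
[CNS_BLEED]
INTRACRANIAL HAEMORRHAGE
CEREBRAL HAEMORRHAGE
INTRACEREBRAL HAEMATOMA
CEREBRAL HAEMATOMA
HAEMORRHAGE INTRACRANIAL
SUBARACHNOID HAEMORRHAGE
SUBDURAL HAEMATOMA
HAEMORRHAGIC STROKE
[GI_BLEED]
GASTROINTESTINAL HAEMORRHAGE
UPPER GASTROINTESTINAL HAEMORRHAGE
LOWER GASTROINTESTINAL HAEMORRHAGE
HAEMATEMESIS
MELAENA
RECTAL HAEMORRHAGE
GASTRIC HAEMORRHAGE
DUODENAL ULCER HAEMORRHAGE
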