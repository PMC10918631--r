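format-version: 1.2
data-version: synthetic/2026-01-01
ontology: mini-disease
remark: Synthetic miniature disease ontology for tests and examples. Term layout imitates the Disease Ontology dialect (DOID accessions, is_a hierarchy, scoped synonyms); contents are a hand-written toy.

[Term]
id: DOID:4
name: disease

[Term]
id: DOID:7
name: disease of anatomical entity
is_a: DOID:4 ! disease

[Term]
id: DOID:162
name: cancer
is_a: DOID:4 ! disease
synonym: "malignant tumor" EXACT []
synonym: "malignant neoplasm" EXACT []

[Term]
id: DOID:1612
name: breast cancer
is_a: DOID:162 ! cancer
synonym: "malignant neoplasm of breast" EXACT []
synonym: "breast tumor" RELATED []

[Term]
id: DOID:3459
name: breast carcinoma
is_a: DOID:1612 ! breast cancer

[Term]
id: DOID:3008
name: invasive ductal carcinoma
is_a: DOID:3459 ! breast carcinoma
synonym: "ductal breast carcinoma" NARROW []

[Term]
id: DOID:1324
name: lung cancer
is_a: DOID:162 ! cancer
synonym: "cancer of lung" EXACT []

[Term]
id: DOID:3908
name: non-small cell lung carcinoma
is_a: DOID:1324 ! lung cancer
synonym: "NSCLC" EXACT []
synonym: "non-small cell lung cancer" EXACT []

[Term]
id: DOID:5409
name: small cell lung carcinoma
is_a: DOID:1324 ! lung cancer
synonym: "SCLC" EXACT []

[Term]
id: DOID:9256
name: colorectal cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:1240
name: leukemia
is_a: DOID:162 ! cancer

[Term]
id: DOID:8552
name: chronic myeloid leukemia
is_a: DOID:1240 ! leukemia
synonym: "CML" EXACT []

[Term]
id: DOID:9119
name: acute myeloid leukemia
is_a: DOID:1240 ! leukemia
synonym: "AML" EXACT []

[Term]
id: DOID:0001816
name: angiosarcoma
is_a: DOID:162 ! cancer

[Term]
id: DOID:0060158
name: obsolete mixed cell type cancer
is_a: DOID:162 ! cancer
is_obsolete: true

[Term]
id: DOID:0060500
name: obsolete heart cancer
is_a: DOID:162 ! cancer
is_obsolete: true

[Term]
id: DOID:114
name: heart disease
is_a: DOID:7 ! disease of anatomical entity

[Term]
id: DOID:1287
name: cardiovascular system disease
is_a: DOID:7 ! disease of anatomical entity

[Term]
id: DOID:2914
name: immune system disease
is_a: DOID:4 ! disease

[Term]
id: DOID:417
name: hypersensitivity reaction type II disease
is_a: DOID:2914 ! immune system disease
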