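# Default matching lexicons: canonical term -> surface variants.
# Variants are matched case-insensitively at word boundaries; a hyphen in a
# variant also matches a space (hyphen/space tolerance).
model_terms:
  organoid:
    class: organoid
    variants: [organoid, organoids]
  enteroid:
    class: organoid
    variants: [enteroid, enteroids]
  colonoid:
    class: organoid
    variants: [colonoid, colonoids]
  assembloid:
    class: organoid
    variants: [assembloid, assembloids]
  gastruloid:
    class: organoid
    variants: [gastruloid, gastruloids]
  iblastoid:
    class: organoid
    variants: [iblastoid, iblastoids]
  tumoroid:
    class: organoid
    oncological: true
    variants: [tumoroid, tumoroids, tumouroid, tumouroids]
  blastoid:
    class: organoid
    never_tumor: true
    requires: embryonic
    variants: [blastoid, blastoids]
  on_chip:
    class: onchip
    variants: [on-chip, on-chips, on-a-chip]
  microphysiological_system:
    class: mps
    variants:
      - microphysiological system
      - microphysiological systems
      - microphysiology system
      - microphysiology systems
      - microphysiologic system
      - microphysiologic systems
      - micro physiological system
      - micro physiological systems
      - micro physiology system
      - micro physiology systems
      - micro physiologic system
      - micro physiologic systems
oncological_terms:
  cancer: [cancer, cancers, cancerous]
  carcinoma: [carcinoma, carcinomas, adenocarcinoma, adenocarcinomas, carcinogenesis]
  adenoma: [adenoma, adenomas]
  sarcoma: [sarcoma, sarcomas, osteosarcoma, chondrosarcoma]
  glioma: [glioma, gliomas, glioblastoma, glioblastomas]
  blastoma: [neuroblastoma, retinoblastoma, medulloblastoma, ameloblastoma]
  leukemia: [leukemia, leukaemia, leukemic]
  lymphoma: [lymphoma, lymphomas]
  myeloma: [myeloma, mesothelioma, melanoma, melanomas]
  neoplasm: [neoplasm, neoplasms, neoplasia, neoplastic]
  malignant: [malignant, malignancy, malignancies]
  metastasis: [metastasis, metastases, metastatic]
  oncology: [oncology, oncological, oncologic]
  tumor: [tumor, tumors, tumour, tumours]
organotypic_processes:
  angiogenesis: [angiogenesis]
  vascularization: [vascularization, vascularisation, vasculature]
  organogenesis: [organogenesis]
  gastrulation: [gastrulation]
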