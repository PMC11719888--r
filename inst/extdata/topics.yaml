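# Nested research-topic lists: first level = topic ids grouped into panels,
# second level = surface variants (writing styles and synonyms). Variants are
# matched case-insensitively at word boundaries with hyphen/space tolerance;
# a topic counts at most once per record.
panels:
  models:
    patient_derived_organoid: [patient-derived organoid, patient-derived organoids, patient-derived tumor organoid, patient-derived tumor organoids, patient-derived tumoroid, patient-derived tumoroids]
    patient_derived_xenograft: [patient-derived xenograft, patient-derived xenografts, pdx]
    biobank: [biobank, biobanks, biobanking, living biobank]
    gemm: [genetically engineered mouse model, genetically engineered mouse models, gemm, gemms]
    murine: [murine, mouse, mice, rat, rats]
    assembloid_model: [assembloid, assembloids]
  therapy:
    personalized_medicine: [personalized medicine, personalised medicine, precision medicine, precision oncology]
    chemotherapy: [chemotherapy, chemotherapeutic, chemotherapeutics]
    chemoresistance: [chemoresistance, chemoresistant, drug resistance, therapy resistance]
    immunotherapy: [immunotherapy, immunotherapies, immunotherapeutic, immune checkpoint, checkpoint inhibitor, checkpoint inhibitors, adoptive cell therapy, monoclonal antibody, monoclonal antibodies, oncolytic virus, oncolytic viruses, car-t cell, car t cells]
    radiotherapy: [radiotherapy, radiation therapy, irradiation, radiosensitivity]
    neoadjuvant_therapy: [neoadjuvant]
  pharmacology:
    drug_development: [drug development, drug discovery, drug screening]
    high_throughput: [high-throughput, high throughput]
    drug_testing: [drug testing, drug sensitivity, drug response]
    drug_delivery: [drug delivery, drug penetration]
  physiology:
    tumorigenesis: [tumorigenesis, tumourigenesis, tumorigenic, oncogenesis]
    cancer_stem_cell: [cancer stem cell, cancer stem cells, cancer stem-like cell, cancer stem-like cells]
    tumor_heterogeneity: [tumor heterogeneity, tumour heterogeneity, intratumoral heterogeneity, intratumor heterogeneity]
    tumor_microenvironment: [tumor microenvironment, tumour microenvironment]
    hypoxia: [hypoxia, hypoxic]
    tumor_angiogenesis: [angiogenesis, angiogenic, neovascularization]
    caf: [cancer-associated fibroblast, cancer-associated fibroblasts]
    metastasis_chain: [epithelial-mesenchymal transition, emt, intravasation, circulating tumor cell, circulating tumor cells, extravasation, mesenchymal-epithelial transition]
    microbiome: [microbiome, microbiota, bacteria, bacterial, bacterium]
  immune_cells:
    til: [tumor-infiltrating lymphocyte, tumor-infiltrating lymphocytes]
    tam: [tumor-associated macrophage, tumor-associated macrophages]
    mdsc: [myeloid-derived suppressor cell, myeloid-derived suppressor cells]
    t_cell: [t cell, t cells, t lymphocyte, t lymphocytes]
    nk_cell: [nk cell, nk cells, natural killer cell, natural killer cells]
    dendritic_cell: [dendritic cell, dendritic cells]
    macrophage: [macrophage, macrophages]
  cellular_processes:
    apoptosis: [apoptosis, apoptotic]
    autophagy: [autophagy, autophagic]
    er_stress: [er stress, endoplasmic reticulum stress]
    reactive_oxygen_species: [reactive oxygen species]
    extracellular_vesicle: [extracellular vesicle, extracellular vesicles, exosome, exosomes]
  techniques:
    gene_editing: [gene editing, genome editing, crispr]
    omics: [scrna-seq, scrna seq, single-cell rna sequencing, single-cell rna-seq, transcriptomics, transcriptomic, proteomics, proteomic, genomics, multi-omics]
    high_content_analysis: [high-content analysis, high-content screening, high-content imaging]
    raman_spectroscopy: [raman spectroscopy, raman]
    bioprinting: [3d bioprinting, bioprinting, bioprinted]
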