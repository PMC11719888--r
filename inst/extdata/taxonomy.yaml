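# Hierarchical organ/substructure taxonomy.
# Levels: 1 = organ system, 2 = organ, 3 = substructure (gastrointestinal and
# neural branches carry the extra level). Every alias must resolve to exactly
# one node. "UN" (unspecified) children are generated automatically for every
# non-leaf node at load time. The `schemes` block gives per-scheme regrouping
# labels (looked up walking from the node toward the root); the shipped
# "incidence" scheme matches cancer-statistics groupings (e.g.,
# cholangiocarcinoma -> liver, islet -> pancreas).
systems:
  - id: gastrointestinal
    label: Gastrointestinal
    aliases: [gastrointestinal, gastro-intestinal, digestive tract]
    schemes: {incidence: large_intestine}
    children:
      - id: intestine
        label: Intestine
        aliases: [intestine, intestinal, bowel, gut]
        schemes: {incidence: large_intestine}
        children:
          - id: large_intestine
            label: Large intestine
            aliases: [large intestine, colon, colonic, colorectal, colorectum, rectosigmoid, cecum, caecum]
            schemes: {incidence: large_intestine}
          - id: rectum
            label: Rectum
            aliases: [rectum, rectal]
            schemes: {incidence: large_intestine}
          - id: small_intestine
            label: Small intestine
            aliases: [small intestine, duodenum, duodenal, ileum, jejunum]
            schemes: {incidence: other}
      - id: stomach
        label: Stomach
        aliases: [stomach, gastric, antrum, pyloric]
        schemes: {incidence: stomach}
      - id: esophagus
        label: Esophagus
        aliases: [esophagus, esophageal, oesophagus, oesophageal]
        schemes: {incidence: esophagus}
  - id: hpb
    label: Hepatic, pancreatic and biliary
    aliases: [hepatopancreatobiliary, hepato-pancreato-biliary]
    schemes: {incidence: liver}
    children:
      - id: liver
        label: Liver
        aliases: [liver, hepatic, hepatocellular, hepatocyte, hepatoma, hepatoblastoma]
        schemes: {incidence: liver}
      - id: pancreas
        label: Pancreas
        aliases: [pancreas, pancreatic]
        schemes: {incidence: pancreas}
      - id: biliary
        label: Biliary
        aliases: [biliary, bile duct, cholangiocarcinoma, cholangiocyte]
        schemes: {incidence: liver}
      - id: gallbladder
        label: Gallbladder
        aliases: [gallbladder, gall bladder]
        schemes: {incidence: other}
      - id: islet
        label: Pancreatic islet
        aliases: [islet, islets]
        schemes: {incidence: pancreas}
  - id: mammary
    label: Mammary gland
    aliases: [mammary]
    schemes: {incidence: mammary}
    children:
      - id: breast
        label: Breast
        aliases: [breast]
        schemes: {incidence: mammary}
  - id: reproductive
    label: Reproductive
    aliases: [reproductive]
    schemes: {incidence: other}
    children:
      - id: prostate
        label: Prostate
        aliases: [prostate, prostatic]
        schemes: {incidence: prostate}
      - id: ovary
        label: Ovary
        aliases: [ovary, ovarian]
        schemes: {incidence: ovary}
      - id: cervix
        label: Cervix
        aliases: [cervix, cervical]
        schemes: {incidence: cervix}
      - id: uterus
        label: Uterus
        aliases: [uterus, uterine, endometrial, endometrium]
        schemes: {incidence: uterus}
      - id: testis
        label: Testis
        aliases: [testis, testicular]
        schemes: {incidence: other}
  - id: neural
    label: Neural
    aliases: [neural, neuronal, nervous system]
    schemes: {incidence: brain}
    children:
      - id: brain
        label: Brain
        aliases: [brain, cerebral, cerebellar, glial]
        schemes: {incidence: brain}
        children:
          - id: pituitary
            label: Pituitary
            aliases: [pituitary]
            schemes: {incidence: brain}
      - id: retina
        label: Retina
        aliases: [retina, retinal]
        schemes: {incidence: other}
  - id: respiratory
    label: Respiratory
    aliases: [respiratory, airway]
    schemes: {incidence: lung}
    children:
      - id: lung
        label: Lung
        aliases: [lung, pulmonary, alveolar, bronchial]
        schemes: {incidence: lung}
  - id: urinary
    label: Urinary
    aliases: [urinary, urothelial]
    schemes: {incidence: other}
    children:
      - id: bladder
        label: Bladder
        aliases: [bladder, vesical]
        schemes: {incidence: bladder}
      - id: kidney
        label: Kidney
        aliases: [kidney, renal, nephron]
        schemes: {incidence: kidney}
  - id: endocrine
    label: Endocrine
    aliases: [endocrine]
    schemes: {incidence: other}
    children:
      - id: thyroid
        label: Thyroid
        aliases: [thyroid]
        schemes: {incidence: thyroid}
      - id: neuroendocrine
        label: Neuroendocrine
        aliases: [neuroendocrine]
        schemes: {incidence: other}
  - id: musculoskeletal
    label: Musculoskeletal
    aliases: [musculoskeletal, muscle]
    schemes: {incidence: other}
    children:
      - id: bone
        label: Bone
        aliases: [bone, osseous, skeletal]
        schemes: {incidence: other}
      - id: tooth
        label: Tooth
        aliases: [tooth, dental]
        schemes: {incidence: other}
      - id: synovium
        label: Synovium
        aliases: [synovium, synovial]
        schemes: {incidence: other}
  - id: blood
    label: Blood and lymphatic
    aliases: [blood, hematopoietic, haematopoietic]
    schemes: {incidence: blood}
    children:
      - id: bone_marrow
        label: Bone marrow
        aliases: [bone marrow, marrow]
        schemes: {incidence: blood}
      - id: lymphatic
        label: Lymphatic
        aliases: [lymphatic, lymph node, lymphoid]
        schemes: {incidence: blood}
  - id: skin
    label: Skin
    aliases: [skin, cutaneous]
    schemes: {incidence: skin}
    children:
      - id: epidermis
        label: Epidermis
        aliases: [epidermis, epidermal, keratinocyte]
        schemes: {incidence: skin}
      - id: melanocyte
        label: Melanocyte
        aliases: [melanocyte, melanocytic]
        schemes: {incidence: skin}
  - id: head_and_neck
    label: Head and neck
    aliases: [head and neck]
    schemes: {incidence: other}
    children:
      - id: tongue
        label: Tongue
        aliases: [tongue, oral, lingual]
        schemes: {incidence: other}
      - id: salivary_gland
        label: Salivary gland
        aliases: [salivary gland, salivary]
        schemes: {incidence: other}
      - id: nasopharynx
        label: Nasopharynx
        aliases: [nasopharynx, nasopharyngeal, hypopharyngeal]
        schemes: {incidence: other}
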