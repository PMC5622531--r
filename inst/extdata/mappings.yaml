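# Terminology mappings for the 15-disease autoimmune panel of the celiac
# case study. ICD-10 entries use the compact catalog syntax: a trailing '*'
# covers all descending nodes, '|' separates alternatives. ATC entries are
# hierarchical prefixes (A10A = insulins, H03AA = thyroid hormones).
# The text-term catalog is a SYNTHETIC reconstruction from disease names
# and common French/English synonyms (the original review catalog is not
# published); patterns are matched case-insensitively on accent-folded text.
diseases:
  - dui: D003922
    name: "Diabetes Mellitus, Type 1"
    icd: ['E10*']
    atc: ['A10A']
    terms:
      - pattern: 'diab\w+'
        label: diabetes
  - dui: D003874
    name: Dermatitis Herpetiformis
    icd: ['L130']
    terms:
      - pattern: 'dermatite\s+herpetiforme'
        label: dermatite herpetiforme
      - pattern: 'dermatitis\s+herpetiformis'
        label: dermatitis herpetiformis
  - dui: D013967
    name: "Thyroiditis, Autoimmune"
    icd: ['E063']
    atc: ['H03AA']
    terms:
      - pattern: 'thyroidit\w+'
        label: thyroiditis
      - pattern: hashimoto
        label: hashimoto
  - dui: D001172
    name: "Arthritis, Rheumatoid"
    icd: ['M069*']
    terms:
      - pattern: 'polyarthrite\s+rhumatoide'
        label: polyarthrite rhumatoide
      - pattern: 'rheumatoid\s+arthritis'
        label: rheumatoid arthritis
  - dui: D008180
    name: "Lupus Erythematosus, Systemic"
    icd: ['M32*']
    terms:
      - pattern: lupus
        label: lupus
  - dui: D009103
    name: Multiple Sclerosis
    icd: ['G35']
    terms:
      - pattern: 'sclerose\s+en\s+plaques'
        label: sclerose en plaques
      - pattern: 'multiple\s+sclerosis'
        label: multiple sclerosis
  - dui: D012859
    name: "Sjogren's Syndrome"
    icd: ['M350']
    terms:
      - pattern: sjogren
        label: sjogren
        fuzzy: true
  - dui: D000224
    name: Addison Disease
    icd: ['E271|E272']
    terms:
      - pattern: addison
        label: addison
  - dui: D001171
    name: "Arthritis, Juvenile"
    icd: ['M089*']
    terms:
      - pattern: 'arthrite\s+juvenile'
        label: arthrite juvenile
      - pattern: 'juvenile\s+arthritis'
        label: juvenile arthritis
  - dui: D019693
    name: "Hepatitis, Autoimmune"
    icd: ['K754']
    terms:
      - pattern: 'hepatite\s+auto-?immune'
        label: hepatite auto-immune
      - pattern: 'autoimmune\s+hepatitis'
        label: autoimmune hepatitis
  - dui: D006111
    name: "Graves' Disease"
    icd: ['E050|E05*']
    terms:
      - pattern: '(basedow|graves)'
        label: basedow / graves
  - dui: D005922
    name: "Glomerulonephritis, IGA"
    icd: ['N0330|N0170']
    terms:
      - pattern: 'nephropathie\s+a\s+iga'
        label: nephropathie a IgA
      - pattern: 'iga\s+nephropathy'
        label: IgA nephropathy
  - dui: D009157
    name: Myasthenia Gravis
    icd: ['G700']
    terms:
      - pattern: 'myastheni\w+'
        label: myasthenia
  - dui: D016884
    name: "Polyendocrinopathies, Autoimmune"
    icd: ['E31*']
    terms:
      - pattern: 'polyendocrinopathi\w+'
        label: polyendocrinopathy
  - dui: D016736
    name: Antiphospholipid Syndrome
    icd: ['D686*']
    terms:
      - pattern: 'antiphospholipid\w+'
        label: antiphospholipid
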