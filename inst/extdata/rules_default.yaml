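# Default rule set: the six published rules for the tumor-site extraction task.
# Keyword matching is case-insensitive for Latin strings and exact for CJK.
schema: 1
lexicons:
  primary_keywords: ["cancer", "CA", "MT", "癌"]
  size_units: ["cm", "mm"]
  density_words: ["density", "shadow", "密度", "影"]
  metastasis_keywords: ["metastasis", "转移"]
  incomplete_parts: ["mediastinum", "纵隔"]
  lymph_tokens: ["lymphnode", "淋巴结"]
site_category: "body"
size_category: "size"
rules:
  - rule_id: segmentation
    target: segmentation
    # split on periods/semicolons; a numbered sentence start opens a new
    # sentence even without a preceding terminator
  - rule_id: primary_site
    target: primary_site
    any_of: [primary_keywords]
  - rule_id: lesion_size
    target: lesion_size
    all_of: [size_units, density_words]
  - rule_id: metastasis_site
    target: metastasis_site
    any_of: [metastasis_keywords]
    region: after_primary_keyword
  - rule_id: special_lymph
    target: special_case
  - rule_id: lesion_conditional
    target: lesion_conditional
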