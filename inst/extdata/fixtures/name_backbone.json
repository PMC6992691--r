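[
  {
    "canonical_name": "Aloe zebrina",
    "authorship": "Baker",
    "family": "Asphodelaceae",
    "usage_key": "2777724",
    "is_synonym": false,
    "accepted_name": "Aloe zebrina"
  },
  {
    "canonical_name": "Aloe platyphylla",
    "authorship": "Baker",
    "family": "Asphodelaceae",
    "usage_key": "2777760",
    "is_synonym": true,
    "accepted_name": "Aloe zebrina"
  },
  {
    "canonical_name": "Sisyrinchium bermudiana",
    "authorship": "L.",
    "family": "Iridaceae",
    "usage_key": "2747310",
    "is_synonym": false,
    "accepted_name": "Sisyrinchium bermudiana"
  }
]
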