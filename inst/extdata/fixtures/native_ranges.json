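[
  {
    "usage_key": "2777724",
    "powo_id": "urn:lsid:ipni.org:names:529234-1",
    "native_codes": ["ANG", "BOT", "MLW", "MOZ", "NAM", "ZAM", "ZIM"],
    "introduced_codes": []
  },
  {
    "usage_key": "2747310",
    "powo_id": "urn:lsid:ipni.org:names:441256-1",
    "native_codes": ["BER"],
    "introduced_codes": ["IRE"]
  }
]
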