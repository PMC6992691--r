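[
  {
    "usage_key": "2777724",
    "decimalLongitude": 21.6527,
    "decimalLatitude": -11.1792,
    "source_id": "occ001",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 20.4539,
    "decimalLatitude": -6.408,
    "source_id": "occ002",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 15.0686,
    "decimalLatitude": -6.2161,
    "source_id": "occ003",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 21.2307,
    "decimalLatitude": -23.4095,
    "source_id": "occ004",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 21.066,
    "decimalLatitude": -20.9913,
    "source_id": "occ005",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 23.1208,
    "decimalLatitude": -20.6954,
    "source_id": "occ006",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 33.0048,
    "decimalLatitude": -13.2874,
    "source_id": "occ007",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 34.857,
    "decimalLatitude": -14.0671,
    "source_id": "occ008",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 33.481,
    "decimalLatitude": -15.3456,
    "source_id": "occ009",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 33.6034,
    "decimalLatitude": -24.5764,
    "source_id": "occ010",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 38.3751,
    "decimalLatitude": -18.8368,
    "source_id": "occ011",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 35.4277,
    "decimalLatitude": -23.918,
    "source_id": "occ012",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 15.1795,
    "decimalLatitude": -18.0772,
    "source_id": "occ013",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 12.8351,
    "decimalLatitude": -27.3591,
    "source_id": "occ014",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 22.8854,
    "decimalLatitude": -21.2489,
    "source_id": "occ015",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 26.309,
    "decimalLatitude": -15.5122,
    "source_id": "occ016",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 27.4782,
    "decimalLatitude": -12.9099,
    "source_id": "occ017",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 31.3412,
    "decimalLatitude": -13.2001,
    "source_id": "occ018",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 28.7607,
    "decimalLatitude": -20.0819,
    "source_id": "occ019",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 31.87,
    "decimalLatitude": -18.2355,
    "source_id": "occ020",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 30.0601,
    "decimalLatitude": -21.2899,
    "source_id": "occ021",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2777724",
    "decimalLongitude": 18.42,
    "decimalLatitude": -33.92,
    "source_id": "occ022",
    "hasGeospatialIssue": true
  },
  {
    "usage_key": "2777724",
    "source_id": "occ023",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2747310",
    "decimalLongitude": -64.7748,
    "decimalLatitude": 32.3144,
    "source_id": "occ024",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2747310",
    "decimalLongitude": -64.7706,
    "decimalLatitude": 32.3249,
    "source_id": "occ025",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2747310",
    "decimalLongitude": -64.72,
    "decimalLatitude": 32.2904,
    "source_id": "occ026",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2747310",
    "decimalLongitude": -64.7759,
    "decimalLatitude": 32.3158,
    "source_id": "occ027",
    "hasGeospatialIssue": false
  },
  {
    "usage_key": "2747310",
    "decimalLongitude": -6.26,
    "decimalLatitude": 53.35,
    "source_id": "occ028",
    "hasGeospatialIssue": false
  }
]
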