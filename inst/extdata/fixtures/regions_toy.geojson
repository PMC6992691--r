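{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "ANG"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [12, -17],
              [23, -17],
              [23, -6],
              [12, -6],
              [12, -17]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "BOT"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [20.5, -26],
              [28.5, -26],
              [28.5, -19],
              [20.5, -19],
              [20.5, -26]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "MLW"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [33, -16],
              [35.5, -16],
              [35.5, -10],
              [33, -10],
              [33, -16]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "MOZ"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [31, -25],
              [40, -25],
              [40, -11],
              [31, -11],
              [31, -25]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "NAM"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [12, -28],
              [24, -28],
              [24, -18],
              [12, -18],
              [12, -28]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "ZAM"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [23, -17],
              [33, -17],
              [33, -9],
              [23, -9],
              [23, -17]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "ZIM"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [25.5, -21.5],
              [32.5, -21.5],
              [32.5, -16],
              [25.5, -16],
              [25.5, -21.5]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "BER"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [-64.9, 32.2],
              [-64.6, 32.2],
              [-64.6, 32.4],
              [-64.9, 32.4],
              [-64.9, 32.2]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "IRE"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [-10.5, 51.4],
              [-6, 51.4],
              [-6, 55.4],
              [-10.5, 55.4],
              [-10.5, 51.4]
            ]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "LEVEL3_COD": "CPP"
      },
      "geometry": {
        "type": "MultiPolygon",
        "coordinates": [
          [
            [
              [17, -35],
              [27, -35],
              [27, -30],
              [17, -30],
              [17, -35]
            ]
          ]
        ]
      }
    }
  ]
}
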