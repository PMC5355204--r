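{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "name": "synthetic peninsula (not a real coastline)"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-158.2, 57.4],
            [-156.6, 57.4],
            [-156.6, 58.05],
            [-157.1, 58.12],
            [-157.55, 58.02],
            [-157.9, 57.75],
            [-158.2, 57.7],
            [-158.2, 57.4]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "name": "synthetic headland at the northern haul-out (not a real coastline)"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-157.55, 58.20],
            [-157.25, 58.20],
            [-157.25, 58.32],
            [-157.55, 58.32],
            [-157.55, 58.20]
          ]
        ]
      }
    }
  ]
}
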