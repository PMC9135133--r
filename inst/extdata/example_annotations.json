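[
  {
    "imagePath": "PH0001_anterior.dcm",
    "imageHeight": 1024,
    "imageWidth": 256,
    "annotatorVotes": 3,
    "shapes": [
      {
        "label": "metastasis",
        "points": [[120, 300], [140, 300], [140, 330], [118, 328]],
        "shape_type": "polygon"
      },
      {
        "label": "metastasis",
        "points": [[60, 700], [75, 705], [66, 730]],
        "shape_type": "polygon"
      },
      {
        "label": "rib",
        "points": [[150, 250], [180, 260], [175, 290], [148, 280]],
        "shape_type": "polygon"
      }
    ]
  },
  {
    "imagePath": "PH0002_anterior.dcm",
    "imageHeight": 1024,
    "imageWidth": 256,
    "annotatorVotes": 2,
    "shapes": [
      {
        "label": "thyroid_carcinoma",
        "points": [[118, 130], [140, 132], [128, 158]],
        "shape_type": "polygon"
      },
      {
        "label": "neck",
        "points": [[110, 115], [146, 115], [146, 170], [110, 170]],
        "shape_type": "polygon"
      }
    ]
  }
]
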