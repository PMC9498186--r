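{
  "image_id": "example_frame",
  "pixels_per_mm": 12.2674,
  "lesion_polygon": [
    [300, 420], [286, 470], [272, 530], [270, 600], [282, 668],
    [308, 724], [350, 762], [404, 780], [462, 774], [514, 744],
    [552, 694], [572, 630], [574, 560], [560, 496], [530, 446],
    [486, 414], [434, 400], [378, 398], [336, 406]
  ],
  "cystic_seeds": [
    {"row": 380, "col": 520, "tolerance": 14},
    {"row": 470, "col": 640, "tolerance": 14}
  ],
  "parenchyma_circles": [
    {"row": 120, "col": 200, "diameter_mm": 5},
    {"row": 120, "col": 420, "diameter_mm": 5},
    {"row": 120, "col": 640, "diameter_mm": 5}
  ]
}
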