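points:
- x: -9
  'y': 21
  sector: superior
  disc_angle: 274
- x: -3
  'y': 21
  sector: superior
  disc_angle: 282
- x: 3
  'y': 21
  sector: superior
  disc_angle: 290
- x: 9
  'y': 21
  sector: superior
  disc_angle: 298
- x: -15
  'y': 15
  sector: superior_nasal
  disc_angle: 268
- x: -9
  'y': 15
  sector: superior
  disc_angle: 278
- x: -3
  'y': 15
  sector: superior
  disc_angle: 286
- x: 3
  'y': 15
  sector: superior
  disc_angle: 294
- x: 9
  'y': 15
  sector: superior
  disc_angle: 300
- x: 15
  'y': 15
  sector: superior
  disc_angle: 306
- x: -21
  'y': 9
  sector: superior_nasal
  disc_angle: 250
- x: -15
  'y': 9
  sector: superior_nasal
  disc_angle: 260
- x: -9
  'y': 9
  sector: superior
  disc_angle: 288
- x: -3
  'y': 9
  sector: superior
  disc_angle: 296
- x: 3
  'y': 9
  sector: superior
  disc_angle: 304
- x: 9
  'y': 9
  sector: superior
  disc_angle: 308
- x: 15
  'y': 9
  sector: temporal
  disc_angle: 220
- x: 21
  'y': 9
  sector: temporal
  disc_angle: 205
- x: -27
  'y': 3
  sector: superior_nasal
  disc_angle: 238
- x: -21
  'y': 3
  sector: superior_nasal
  disc_angle: 246
- x: -15
  'y': 3
  sector: superior_nasal
  disc_angle: 256
- x: -9
  'y': 3
  sector: central
  disc_angle: 320
- x: -3
  'y': 3
  sector: central
  disc_angle: 330
- x: 3
  'y': 3
  sector: central
  disc_angle: 340
- x: 9
  'y': 3
  sector: central
  disc_angle: 350
- x: 21
  'y': 3
  sector: temporal
  disc_angle: 190
- x: -27
  'y': -3
  sector: inferior_nasal
  disc_angle: 122
- x: -21
  'y': -3
  sector: inferior_nasal
  disc_angle: 114
- x: -15
  'y': -3
  sector: inferior_nasal
  disc_angle: 104
- x: -9
  'y': -3
  sector: central
  disc_angle: 40
- x: -3
  'y': -3
  sector: central
  disc_angle: 30
- x: 3
  'y': -3
  sector: central
  disc_angle: 20
- x: 9
  'y': -3
  sector: central
  disc_angle: 10
- x: 21
  'y': -3
  sector: temporal
  disc_angle: 170
- x: -21
  'y': -9
  sector: inferior_nasal
  disc_angle: 110
- x: -15
  'y': -9
  sector: inferior_nasal
  disc_angle: 100
- x: -9
  'y': -9
  sector: inferior
  disc_angle: 72
- x: -3
  'y': -9
  sector: inferior
  disc_angle: 64
- x: 3
  'y': -9
  sector: inferior
  disc_angle: 56
- x: 9
  'y': -9
  sector: inferior
  disc_angle: 52
- x: 15
  'y': -9
  sector: temporal
  disc_angle: 140
- x: 21
  'y': -9
  sector: temporal
  disc_angle: 155
- x: -15
  'y': -15
  sector: inferior_nasal
  disc_angle: 92
- x: -9
  'y': -15
  sector: inferior
  disc_angle: 82
- x: -3
  'y': -15
  sector: inferior
  disc_angle: 74
- x: 3
  'y': -15
  sector: inferior
  disc_angle: 66
- x: 9
  'y': -15
  sector: inferior
  disc_angle: 60
- x: 15
  'y': -15
  sector: inferior
  disc_angle: 54
- x: -9
  'y': -21
  sector: inferior
  disc_angle: 86
- x: -3
  'y': -21
  sector: inferior
  disc_angle: 78
- x: 3
  'y': -21
  sector: inferior
  disc_angle: 70
- x: 9
  'y': -21
  sector: inferior
  disc_angle: 62
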