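{
  "space": "lab",
  "source": "synthetic reference palette: one swatch per Fitzpatrick class with evenly spaced lightness (L = 77..37, step 8) and representative skin chroma, each swatch lying inside its del Bino ITA band (boundaries 55, 41, 28, 10, -30 degrees); not measured from any subject or device",
  "colors": [
    { "fst": 1, "lab": [77.0, 9.0, 14.0] },
    { "fst": 2, "lab": [69.0, 10.0, 17.0] },
    { "fst": 3, "lab": [61.0, 11.0, 19.0] },
    { "fst": 4, "lab": [53.0, 12.0, 13.0] },
    { "fst": 5, "lab": [45.0, 13.0, 17.0] },
    { "fst": 6, "lab": [37.0, 12.0, 13.0] }
  ]
}
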