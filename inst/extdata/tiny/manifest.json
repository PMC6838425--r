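{
  "preset": "tiny",
  "seed": 20,
  "n_patients": 3,
  "sections_per_patient": 1,
  "n_sections": 3,
  "n_cells": 2170
}
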