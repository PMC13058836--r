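{
  "_comment": "Illustrative synthetic cost constants (common currency units). Chosen so that NGS undercuts Sanger from 81 samples when indexing-primer synthesis is included and from 8 samples with an existing primer set.",
  "sanger_per_sample": 150,
  "ngs_per_sample": 10,
  "ngs_fixed": 1000,
  "primer_unit_cost": 570
}
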