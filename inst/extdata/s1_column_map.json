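{
  "_comment": "Template column map for a Malacolog-style species export. The exact headers of a given export vary; edit the right-hand values to match your file and pass the map to read_species_table(). This mapping is a synthetic template, not a copy of any published file's schema.",
  "taxon_name": "taxon",
  "genus": "genus",
  "shell_length_mm": "length_mm",
  "depth_min_m": "depth_min_m",
  "depth_max_m": "depth_max_m"
}
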