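{
  "description": "Published genome-annotation summary counts for the Flammulina velutipes KACC42780 genome project.",
  "total_genes": 12218,
  "never_expressed_genes": 1030,
  "assembly_length_bp": 35600000,
  "unique_genes": 5751,
  "inparalog_genes": 2688,
  "nr_annotated_genes": 9051,
  "kog_annotated_genes": 9589
}
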