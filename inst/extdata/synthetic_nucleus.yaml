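# Synthetic example configuration: a diploid stem-cell-like nucleus with two
# membraneless organelle classes, one chromatin-rich (heterochromatin-focus
# style, DAPI-biased) and one RNA-rich (nucleolus style). All numbers are
# illustrative synthetic values, not measurements.
nucleus:
  nucleus_volume: 450.0
organelles:
  - name: chromatin_focus
    volume: 3.0
    count_per_nucleus: 10
    rna_enrichment: 0.5
    nucleosome_enrichment: 4.5
    rna_length: 2790
    dapi_bias_correction: true
  - name: rna_body
    volume: 40.0
    count_per_nucleus: 2
    rna_enrichment: 12.0
    nucleosome_enrichment: 0.3
    rna_length: 14000
calibration:
  - {protein: anchor_a, measured_copies: 218000, ibaq: 1800}
  - {protein: anchor_b, measured_copies: 120000, ibaq: 1000}
  - {protein: anchor_c, measured_copies: 60000, ibaq: 510}
  - {protein: anchor_h4, measured_copies: 53763441, ibaq: 450000}
species_file: synthetic_species.tsv
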