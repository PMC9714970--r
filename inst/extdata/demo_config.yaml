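# Demo analysis: render a phantom, quantify it, call vesicles, and run the
# Fisher exact test on the published enlarged-lysosome contingency counts
# (39/184 wild-type vs 134/236 mutant hair cells).
seed: 7
stages:
  phantom:
    n_cells: 1
    enlarged_fraction: 1
    lysosome_count: 2
    probes:
      - name: PM
        membrane_density: 1
        enrichment: 1
        cyto_density: 0.05
        lysosome_density: 0
      - name: Lamp1
        membrane_density: 0.05
        enrichment: 1
        cyto_density: 0.02
        lysosome_density: 2
  quantify:
    channel: Lamp1
  vesicles:
    diameter_threshold_um: 2.0
  fisher:
    counts: [39, 145, 134, 102]
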