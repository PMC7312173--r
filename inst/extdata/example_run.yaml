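# Example slidedamage run config: simulate a treated slide, run the full
# pipeline, and write DR maps per phase.
#   Rscript inst/cli/slidedamage run --config inst/extdata/example_run.yaml
run_dir: slidedamage_run
seed: 1
pixel_size: 0.5        # micrometres per pixel (20x scan)
fast_axis: cols        # each image row is one scan line
simulate:
  n_nuclei: 2000
  confluence: 0.25
  phase_mix: {G1: 0.55, S: 0.12, G2: 0.27, M2: 0.015, M3: 0.015, M4: 0.015, M5: 0.015}
  artifacts:
    damage: {mode: ring, amplitude: 0.7, ring_radius_um: 1000, ring_width_um: 300}
segmentation: {sigma: 1, min_area: 30, window: 1024, method: seeded_watershed}
correction: {lowess_span: 0.3, block_mm: 1.0, pct: [2, 4], flatten_gh2ax: true}
features: {fourier_k: 16, shells: 4, levels: 64, granularity: 16}
classify: {train_synthetic: true, n_per_class: 500}
cohort: {role: treated, incubation_h: 1}
damage_map:
  enable: true
  center_x_um: 2500    # treatment location (slide frame, micrometres)
  center_y_um: 2500
  diameter_mm: 4       # 18 for a full-coverslip scan
  bin_mm: 0.25
  stat: DR
  threshold: 75
  phases: [all, G1, S, G2]
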