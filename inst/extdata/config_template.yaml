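# hcscreen run configuration template.
# Every key is optional; omitted keys fall back to the package defaults
# shown here (load with read_run_config(), which completes the defaults).

library:
  n_ligases: 327          # ubiquitin-ligase genes in the library
  n_dubs: 92              # deubiquitinase genes
  sirnas_per_gene: 3      # independent siRNAs per gene (one plate set each)
  effect_config:
    fraction_down: 0.05   # fraction of genes with an implanted decrease
    fraction_up: 0.05     # fraction with an implanted increase
    delta_magnitude: 0.6931  # |effect| on the log scale (ln 2 = two-fold)
  efficacy_range: [0.6, 0.95]  # per-siRNA knockdown efficacy, uniform

layout:
  plate_format: [8, 12]   # rows, columns (96-well)
  samples_per_plate: 80
  controls:
    n_negative: 4         # negative-control wells per plate
    n_positive: 8         # positive-control wells per plate
    n_background: 4       # no-primary-antibody background wells per plate

model:                    # per-cell log-normal intensity model
  mu0: 4.6052             # baseline log-intensity, ln(100)
  tau: 1.0986             # treatment effect, ln(3)
  sigma_cell: 0.5         # cell-to-cell SD of log-intensity
  sigma_well: 0.1         # well-to-well SD
  sigma_plate: 0.15       # SD of per-plate effects
  lambda_cells: 500       # Poisson mean cells per well
  background_level: 5     # median signal in background wells
  sigma_background: 0.2
  positive_delta: 1.0986  # implanted effect of positive controls, ln(3)
  hoechst_level: 500      # nuclear-stain channel median
  sigma_hoechst: 0.2

treated: true             # simulate under genotoxic treatment
mode: wells               # "wells" (fast, measurement-level) or "images"

image:                    # rendering (images mode only)
  width: 256
  height: 256
  psf_sigma: 0.5          # Gaussian point-spread SD, pixels
  read_noise_sd: 2
  offset: 10              # camera offset counts
  radius_mean: 10         # nucleus radius, pixels
  radius_sd: 1

segmentation:
  threshold_method: otsu  # or "fixed" with `threshold`
  min_area: 40            # pixels
  max_area: 5000
  connectivity: 8
  exclude_border: true

min_nuclei: 50            # wells below this count are flagged invalid

normalize:
  include_controls: false # controls contribute to plate median/MAD?
  mad_scaled: false       # multiply MAD by 1.4826?
  scope: per_plate        # background subtraction: per_plate or global
  min_wells: 8

hits:
  threshold: 2            # per-siRNA |z| hit threshold (inclusive)
  min_pass: 2             # concordant passing siRNAs for a candidate
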