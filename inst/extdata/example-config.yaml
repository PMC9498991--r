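# Example pipeline configuration.  Every key is optional; omitted keys take
# the documented defaults (the published study conditions).
seed: 1
cohort_size: 200
output_dir: radiosens-output
stages:
  survival: true
  coefficients: true
  discrimination: true
  prediction: true
ground_truth:
  dose: 2               # Gy per session
  dsb_per_gy: 40        # DSB induced per Gy per cell
  noise_scale: 1        # 0 reproduces the laws exactly
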