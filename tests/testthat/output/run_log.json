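{
  "max_error_rate": 0.05,
  "jump_threshold_mm": 10,
  "stationary_threshold_px": 2,
  "bin_width_s": 30,
  "occupancy_bin_s": 60,
  "align": "start",
  "min_stop_duration_s": 2,
  "alpha": 0.05,
  "segmentation_threshold": 0.0313725490196078,
  "notices": ["QC-excluded flies dropped from analytics: fly00, fly01, fly02, fly03", "all flies excluded by QC; analytics skipped"]
}
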