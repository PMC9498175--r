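# Illustrative preset for Super Kernel Basmati Brown. Broken thresholds and HSV ranges are NOT
# trade standards: every buyer grades to their own limits. Tune against
# reference kernels before production use.
name: "Super Kernel Basmati Brown"
broken_threshold_mm: 5.5
yellow_range:
  lower: [20, 80, 80]
  upper: [35, 255, 255]
chalky_range:
  lower: [0, 0, 200]
  upper: [179, 40, 255]
yellow_flag_threshold: 0.30
chalky_flag_threshold: 0.30
sanity_length_mm: 15
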