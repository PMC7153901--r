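# LST-1 / SYGL-1 auxin time-course panel, distal 25 cd.
# Peak = mean over 2-5 cd; t0 LST-1 peak anchors normalization at 100.
#   lst1: peak falls 5-fold by 2 h and 10-fold by 4 h of auxin treatment
#   sygl1: peak falls 3-fold by 2 h and 10-fold by 4 h
# Each later time point is the t0 profile scaled by the configured fold drop.
name: figS10
protein: LST-1/SYGL-1
max_cd: 25
peak_window: [2, 5]
peak_stat: mean
base_cd: 25
control: lst1_t0
untagged: n2
gain: 3.0
background_level: 20.0
noise_sd: 6.0
n_germlines: 20
genotypes:
  n2:
    tagged: false
    breakpoints: [[1, 0], [25, 0]]
  lst1_t0:
    breakpoints: [[1, 95], [2, 100], [5, 100], [10, 10], [25, 5]]
  lst1_t2:
    breakpoints: [[1, 19], [2, 20], [5, 20], [10, 2], [25, 1]]
  lst1_t4:
    breakpoints: [[1, 9.5], [2, 10], [5, 10], [10, 1], [25, 0.5]]
  sygl1_t0:
    breakpoints: [[1, 90], [2, 100], [5, 100], [12, 8], [25, 4]]
  sygl1_t2:
    breakpoints: [[1, 30], [2, 33.333333], [5, 33.333333], [12, 2.666667], [25, 1.333333]]
  sygl1_t4:
    breakpoints: [[1, 9], [2, 10], [5, 10], [12, 0.8], [25, 0.4]]
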