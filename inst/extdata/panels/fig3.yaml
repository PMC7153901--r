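# LAG-1 genotype panel, mid-L4 germlines, distal 25 cd.
# Levels are on the normalized scale (wild-type control peak at 4 cd = 100)
# and encode the panel's quantitative relationships:
#   wt: peak 100 at 4 cd, proximal base 100/7 at 25 cd (7-fold peak-to-base drop,
#       base ~15% of peak)
#   gld2_gld1: peak elevated ~25% (125); base elevated 4.5-fold over wt (64.2857)
#   gld2_gld1_glp1: pathway null, peak region at 39% of the gld2_gld1 peak
#       (48.75), with a shallow distal-to-proximal rise
#   gld2_gld1_lst1_sygl1: targets null, peak at 70% of the gld2_gld1 peak (87.5)
# The generator multiplies levels by `gain` (camera units per normalized unit)
# and adds `background_level` (untagged staining) to produce raw profiles.
name: fig3
protein: LAG-1
max_cd: 25
peak_window: [4, 4]
peak_stat: mean
base_cd: 25
control: wt
untagged: n2
gain: 3.0
background_level: 20.0
noise_sd: 6.0
n_germlines: 20
genotypes:
  n2:
    tagged: false
    breakpoints: [[1, 0], [25, 0]]
  wt:
    breakpoints: [[1, 97], [4, 100], [5, 95], [17, 14.285714], [25, 14.285714]]
  gld2_gld1:
    breakpoints: [[1, 121], [4, 125], [5, 119], [14, 64.285714], [25, 64.285714]]
  gld2_gld1_glp1:
    breakpoints: [[1, 46], [4, 48.75], [25, 58]]
  gld2_gld1_lst1_sygl1:
    breakpoints: [[1, 84], [4, 87.5], [5, 83], [14, 64.285714], [25, 64.285714]]
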