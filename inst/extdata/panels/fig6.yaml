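# FBF-2 genotype panel, young-adult germlines, distal 35 cd.
# Peak = maximum of the mean profile within 8-13 cd; base at 35 cd.
#   wt: peak plateau 100 over 8-13 cd, base 25 (4-fold peak-to-base)
#   gld2_gld1: peak 80 (~80% of wt), flat base 20 from ~18 cd (again 4-fold)
#   gld2_gld1_glp1 / gld2_gld1_lst1_sygl1: flat 12 = 15% of the gld2_gld1
#       reference peak (GLP-1-independent remainder; the lst-1/sygl-1 null
#       matches the pathway null, so the whole dependent fraction is
#       target-mediated)
name: fig6
protein: FBF-2
max_cd: 35
peak_window: [8, 13]
peak_stat: max
base_cd: 35
control: wt
untagged: n2
gain: 3.0
background_level: 20.0
noise_sd: 6.0
n_germlines: 20
genotypes:
  n2:
    tagged: false
    breakpoints: [[1, 0], [35, 0]]
  wt:
    breakpoints: [[1, 60], [8, 100], [13, 100], [35, 25]]
  gld2_gld1:
    breakpoints: [[1, 50], [8, 80], [13, 80], [18, 20], [35, 20]]
  gld2_gld1_glp1:
    breakpoints: [[1, 12], [35, 12]]
  gld2_gld1_lst1_sygl1:
    breakpoints: [[1, 12], [35, 12]]
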