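# LAG-1 proximal-repression panel: single vs double meiotic-entry-pathway
# nulls, distal 25 cd, same scale as fig3 (wt control peak = 100).
#   wt base 100/7 at 25 cd
#   gld1 single null: base elevated ~3-fold (42.857)
#   gld2 single null: base unchanged from wt
#   gld2_gld1 double null: base elevated 4.5-fold (64.2857), peak 125
name: figS3
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
  gld1:
    breakpoints: [[1, 99], [4, 103], [5, 98], [14, 42.857143], [25, 42.857143]]
  gld2:
    breakpoints: [[1, 96], [4, 100], [5, 95], [17, 14.285714], [25, 14.285714]]
  gld2_gld1:
    breakpoints: [[1, 121], [4, 125], [5, 119], [14, 64.285714], [25, 64.285714]]
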