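# Demonstration run: fully synthetic inputs with a planted enrichment of
# the DEG list "deg_planted" for the high_H2A.Z track (theta = 3), a null
# DEG list as negative control, and a Monte Carlo null at reduced K.
seed: 42
alpha: 0.05
generator:
  universe_size: 27416
  tracks:
    - {label: high_H2A.Z, size: 4081}
    - {label: H3K9ac, size: 1984, overlap_with: high_H2A.Z, overlap: 850}
  deg_lists:
    - {label: deg_planted, size: 800, theta: 3, track: high_H2A.Z}
    - {label: deg_null, size: 800, theta: 1, track: high_H2A.Z}
  rho: 0.9
  phenotype:
    n: 15
    sigma: 0.5
    betaInt: -1.5
comparisons:
  - {a: deg_planted, b: high_H2A.Z}
  - {a: deg_null, b: high_H2A.Z}
  - {a: deg_planted, b: deg_null}
stratified:
  - {a: deg_planted, tracks: [H3K9ac, high_H2A.Z], intersect: true}
null_calibration:
  K: 2000
  size_range: [500, 2000]
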