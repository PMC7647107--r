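command: frobnicate
config:
  paths:
    survey: ~
    codebook: ~
    network_spec: ~
    out_dir: hwtbbn-out
  learning:
    prior_ess: 1.0
    tol: 1.0e-06
    max_iter: 500.0
    init: uniform
    seed: 0.0
  cv:
    k: 10.0
    seed: 0.0
  simulate:
    'n': 202.0
    seed: 1.0
    sigma: 1.2
    missing_rate: 0.05
  report:
    digits: 0.0
r_version: 4.3.3
package_version: 0.1.0

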