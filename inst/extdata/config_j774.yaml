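# Bundled fixture configuration: small J774A.1-style simulated screen
# (8 compounds x 3 doses, n = 6 replicate plates).
preset: j774
doses: [0.1, 1, 5]
n_replicates: 6
compounds: [amiodarone, amitriptyline, amikacin, salbutamol, tiotropium,
            budesonide, staurosporine, roflumilast]
seed: 1
threshold_pct: 10
detachment_pct: 50
quartile_convention: tukey
cluster_k: 2
cluster_dose: 5
jitter: 0.05
plots: true
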