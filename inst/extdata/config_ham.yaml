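# Bundled fixture configuration: primary human alveolar macrophage-style
# screen (5 donors, two dose levels of selected compounds).
preset: ham
doses: [5, 10]
n_replicates: 5
compounds: [amiodarone, amitriptyline, staurosporine, camptothecin,
            salbutamol, indacaterol]
seed: 1
threshold_pct: 10
detachment_pct: 50
quartile_convention: tukey
cluster_k: 2
cluster_dose: 5
jitter: 0.05
plots: true
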