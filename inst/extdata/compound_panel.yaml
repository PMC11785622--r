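# Compound panel for simulated screens: inhaled-drug classes plus CAD and
# apoptosis-inducer reference groups. Effect templates are phenomenological
# (cad / apoptosis / corticosteroid / inert); lipophilicity_rank is a
# SYNTHETIC within-class ordering used only for deterministic heatmap row
# ordering — it is not a measured or predicted logD value.
compounds:
  - {name: amiodarone,     class: CAD,               lipophilicity_rank: 4, template: cad}
  - {name: amitriptyline,  class: CAD,               lipophilicity_rank: 2, template: cad}
  - {name: bedaquiline,    class: CAD,               lipophilicity_rank: 3, template: cad}
  - {name: chloroquine,    class: CAD,               lipophilicity_rank: 1, template: cad}
  - {name: amikacin,       class: antibiotic,        lipophilicity_rank: 1, template: inert}
  - {name: azithromycin,   class: antibiotic,        lipophilicity_rank: 3, template: inert}
  - {name: colistin,       class: antibiotic,        lipophilicity_rank: 2, template: inert}
  - {name: gentamycin,     class: antibiotic,        lipophilicity_rank: 0, template: inert}
  - {name: salbutamol,     class: beta-agonist,      lipophilicity_rank: 0, template: inert}
  - {name: formoterol,     class: beta-agonist,      lipophilicity_rank: 1, template: corticosteroid}
  - {name: salmeterol,     class: beta-agonist,      lipophilicity_rank: 3, template: cad}
  - {name: indacaterol,    class: beta-agonist,      lipophilicity_rank: 2, template: cad}
  - {name: ipratropium,    class: anticholinergic,   lipophilicity_rank: 0, template: inert}
  - {name: glycopyrrolate, class: anticholinergic,   lipophilicity_rank: 1, template: inert}
  - {name: tiotropium,     class: anticholinergic,   lipophilicity_rank: 2, template: inert}
  - {name: aclidinium,     class: anticholinergic,   lipophilicity_rank: 3, template: corticosteroid}
  - {name: camptothecin,   class: apoptosis inducer, lipophilicity_rank: 0, template: corticosteroid}
  - {name: staurosporine,  class: apoptosis inducer, lipophilicity_rank: 1, template: apoptosis}
  - {name: actinomycin_d,  class: apoptosis inducer, lipophilicity_rank: 2, template: apoptosis}
  - {name: budesonide,     class: corticosteroid,    lipophilicity_rank: 1, template: corticosteroid}
  - {name: beclomethasone, class: corticosteroid,    lipophilicity_rank: 0, template: corticosteroid}
  - {name: ciclesonide,    class: corticosteroid,    lipophilicity_rank: 3, template: corticosteroid}
  - {name: mometasone,     class: corticosteroid,    lipophilicity_rank: 2, template: corticosteroid}
  - {name: roflumilast,    class: miscellaneous,     lipophilicity_rank: 0, template: inert}
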