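# Global cancer-statistics constants used by the incidence/mortality
# comparison export. Values are configuration inputs in the style of global
# cancer statistics compendia (new cases / deaths, thousands, ~2020); the
# comparison only uses within-column proportions, so units cancel. Groups are
# keyed by the "incidence" regrouping scheme of the shipped taxonomy.
groups:
  large_intestine: {incidence: 1932, mortality: 935}
  stomach: {incidence: 1089, mortality: 769}
  esophagus: {incidence: 604, mortality: 544}
  liver: {incidence: 906, mortality: 830}
  pancreas: {incidence: 496, mortality: 466}
  mammary: {incidence: 2261, mortality: 685}
  prostate: {incidence: 1414, mortality: 375}
  lung: {incidence: 2207, mortality: 1796}
  cervix: {incidence: 604, mortality: 342}
  uterus: {incidence: 417, mortality: 97}
  ovary: {incidence: 314, mortality: 207}
  bladder: {incidence: 573, mortality: 213}
  kidney: {incidence: 431, mortality: 179}
  brain: {incidence: 308, mortality: 251}
  thyroid: {incidence: 586, mortality: 44}
  blood: {incidence: 1278, mortality: 711}
  skin: {incidence: 325, mortality: 57}
  other: {incidence: 2000, mortality: 1000}
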