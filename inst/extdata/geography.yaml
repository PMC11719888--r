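# Country/region gazetteer with name variants, an approximate population
# snapshot (persons, 2023 reference year) and European Research Area (ERA)
# membership (EU-27 incl. the former member UK, plus 18 associated countries).
# Hong Kong and Taiwan are gazetteer entries in their own right (regions).
snapshot: 2023
countries:
  - {name: USA, variants: [USA, United States of America, United States, U.S.A.], population: 334900000, era: false}
  - {name: UK, variants: [UK, United Kingdom, England, Scotland, Wales, Northern Ireland, U.K.], population: 67600000, era: true}
  - {name: China, variants: [China, "People's Republic of China", P.R. China, PR China], population: 1411000000, era: false}
  - {name: Japan, population: 124500000, era: false}
  - {name: South Korea, variants: [South Korea, Republic of Korea, Korea], population: 51700000, era: false}
  - {name: Taiwan, population: 23400000, era: false}
  - {name: Hong Kong, population: 7500000, era: false}
  - {name: Singapore, population: 5900000, era: false}
  - {name: India, population: 1428000000, era: false}
  - {name: Australia, population: 26400000, era: false}
  - {name: New Zealand, population: 5200000, era: false}
  - {name: Canada, population: 40100000, era: false}
  - {name: Brazil, population: 216400000, era: false}
  - {name: Mexico, population: 128500000, era: false}
  - {name: Argentina, population: 45800000, era: false}
  - {name: Russia, variants: [Russia, Russian Federation], population: 144400000, era: false}
  - {name: Iran, population: 89200000, era: false}
  - {name: Saudi Arabia, population: 36900000, era: false}
  - {name: Egypt, population: 112700000, era: false}
  - {name: South Africa, population: 60400000, era: false}
  - {name: Thailand, population: 71800000, era: false}
  - {name: Malaysia, population: 34300000, era: false}
  - {name: Vietnam, variants: [Vietnam, Viet Nam], population: 98900000, era: false}
  - {name: Indonesia, population: 277500000, era: false}
  - {name: Austria, population: 9100000, era: true}
  - {name: Belgium, population: 11800000, era: true}
  - {name: Bulgaria, population: 6400000, era: true}
  - {name: Croatia, population: 3900000, era: true}
  - {name: Cyprus, population: 1300000, era: true}
  - {name: Czech Republic, variants: [Czech Republic, Czechia], population: 10900000, era: true}
  - {name: Denmark, population: 5900000, era: true}
  - {name: Estonia, population: 1400000, era: true}
  - {name: Finland, population: 5600000, era: true}
  - {name: France, population: 68200000, era: true}
  - {name: Germany, population: 84500000, era: true}
  - {name: Greece, population: 10400000, era: true}
  - {name: Hungary, population: 9600000, era: true}
  - {name: Ireland, population: 5300000, era: true}
  - {name: Italy, population: 58900000, era: true}
  - {name: Latvia, population: 1900000, era: true}
  - {name: Lithuania, population: 2800000, era: true}
  - {name: Luxembourg, population: 660000, era: true}
  - {name: Malta, population: 540000, era: true}
  - {name: Netherlands, variants: [Netherlands, The Netherlands, Holland], population: 17800000, era: true}
  - {name: Poland, population: 36800000, era: true}
  - {name: Portugal, population: 10500000, era: true}
  - {name: Romania, population: 19100000, era: true}
  - {name: Slovakia, population: 5400000, era: true}
  - {name: Slovenia, population: 2100000, era: true}
  - {name: Spain, population: 48300000, era: true}
  - {name: Sweden, population: 10500000, era: true}
  - {name: Albania, population: 2800000, era: true}
  - {name: Armenia, population: 2800000, era: true}
  - {name: Bosnia and Herzegovina, population: 3200000, era: true}
  - {name: Faroe Islands, population: 54000, era: true}
  - {name: Georgia, population: 3700000, era: true}
  - {name: Iceland, population: 390000, era: true}
  - {name: Israel, population: 9700000, era: true}
  - {name: Kosovo, population: 1700000, era: true}
  - {name: Moldova, population: 2500000, era: true}
  - {name: Montenegro, population: 620000, era: true}
  - {name: Morocco, population: 37800000, era: true}
  - {name: North Macedonia, population: 1800000, era: true}
  - {name: Norway, population: 5500000, era: true}
  - {name: Serbia, population: 6600000, era: true}
  - {name: Switzerland, population: 8800000, era: true}
  - {name: Tunisia, population: 12500000, era: true}
  - {name: Turkey, variants: [Turkey, Turkiye, Türkiye], population: 85300000, era: true}
  - {name: Ukraine, population: 36700000, era: true}
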