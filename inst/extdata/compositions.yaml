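# Compositions of the simulated aquatic solutions: five terpenoid-water
# systems and ten hyperbranched-polymer + terpenoid systems.
# Note: gamma-terpinene is listed with 22 atoms/molecule in the terpenoid-only
# table and 26 atoms/molecule in the polymer-mixture table; both values are
# kept per-table exactly as published (the source does not reconcile them) so
# that each printed atom total is reproduced. No chemical correction is made.
systems:
  car:
    notes: carvacrol in water
    species:
      - {name: carvacrol, role: terpenoid, molecules: 213, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 9403, atoms_per_molecule: 3}
  thy:
    notes: thymol in water
    species:
      - {name: thymol, role: terpenoid, molecules: 209, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 8526, atoms_per_molecule: 3}
  ter:
    notes: gamma-terpinene in water (22 atoms/molecule as published)
    species:
      - {name: gamma-terpinene, role: terpenoid, molecules: 245, atoms_per_molecule: 22}
      - {name: water, role: water, molecules: 8207, atoms_per_molecule: 3}
  cym:
    notes: p-cymene in water
    species:
      - {name: p-cymene, role: terpenoid, molecules: 243, atoms_per_molecule: 24}
      - {name: water, role: water, molecules: 8279, atoms_per_molecule: 3}
  mix:
    notes: four-terpenoid mixture in realistic proportions
    species:
      - {name: carvacrol, role: terpenoid, molecules: 1704, atoms_per_molecule: 25}
      - {name: gamma-terpinene, role: terpenoid, molecules: 144, atoms_per_molecule: 22}
      - {name: p-cymene, role: terpenoid, molecules: 168, atoms_per_molecule: 24}
      - {name: thymol, role: terpenoid, molecules: 64, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 75224, atoms_per_molecule: 3}
  hbpei8_7:
    notes: HBPEI (1:7), 8 chains; HBPEI partially protonated (+14 e/chain)
    species:
      - {name: HBPEI, role: polymer, molecules: 8, atoms_per_molecule: 355, charge: 14}
      - {name: carvacrol, role: terpenoid, molecules: 56, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 34040, atoms_per_molecule: 3}
      - {name: Cl, role: ion, molecules: 112, atoms_per_molecule: 1, charge: -1}
  hbpei8_14:
    notes: HBPEI (1:14), 8 chains
    species:
      - {name: HBPEI, role: polymer, molecules: 8, atoms_per_molecule: 355, charge: 14}
      - {name: carvacrol, role: terpenoid, molecules: 112, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 34040, atoms_per_molecule: 3}
      - {name: Cl, role: ion, molecules: 112, atoms_per_molecule: 1, charge: -1}
  hbpei8_21:
    notes: HBPEI (1:21), 8 chains
    species:
      - {name: HBPEI, role: polymer, molecules: 8, atoms_per_molecule: 355, charge: 14}
      - {name: carvacrol, role: terpenoid, molecules: 168, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 34040, atoms_per_molecule: 3}
      - {name: Cl, role: ion, molecules: 112, atoms_per_molecule: 1, charge: -1}
  hbpei27_7:
    notes: HBPEI (1:7), 27 chains
    species:
      - {name: HBPEI, role: polymer, molecules: 27, atoms_per_molecule: 355, charge: 14}
      - {name: carvacrol, role: terpenoid, molecules: 189, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 114885, atoms_per_molecule: 3}
      - {name: Cl, role: ion, molecules: 378, atoms_per_molecule: 1, charge: -1}
  hbpei27_mix:
    notes: HBPEI, 27 chains, four-terpenoid mixture (27:189:18:15:7)
    species:
      - {name: HBPEI, role: polymer, molecules: 27, atoms_per_molecule: 355, charge: 14}
      - {name: carvacrol, role: terpenoid, molecules: 189, atoms_per_molecule: 25}
      - {name: p-cymene, role: terpenoid, molecules: 18, atoms_per_molecule: 24}
      - {name: gamma-terpinene, role: terpenoid, molecules: 15, atoms_per_molecule: 26}
      - {name: thymol, role: terpenoid, molecules: 7, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 114885, atoms_per_molecule: 3}
      - {name: Cl, role: ion, molecules: 378, atoms_per_molecule: 1, charge: -1}
  hpg8_10:
    notes: HPG (1:10), 8 chains; HPG electrically neutral, no counterions
    species:
      - {name: HPG, role: polymer, molecules: 8, atoms_per_molecule: 210}
      - {name: carvacrol, role: terpenoid, molecules: 80, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 17752, atoms_per_molecule: 3}
  hpg8_20:
    notes: HPG (1:20), 8 chains
    species:
      - {name: HPG, role: polymer, molecules: 8, atoms_per_molecule: 210}
      - {name: carvacrol, role: terpenoid, molecules: 160, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 17752, atoms_per_molecule: 3}
  hpg8_30:
    notes: HPG (1:30), 8 chains
    species:
      - {name: HPG, role: polymer, molecules: 8, atoms_per_molecule: 210}
      - {name: carvacrol, role: terpenoid, molecules: 240, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 17752, atoms_per_molecule: 3}
  hpg27_10:
    notes: HPG (1:10), 27 chains
    species:
      - {name: HPG, role: polymer, molecules: 27, atoms_per_molecule: 210}
      - {name: carvacrol, role: terpenoid, molecules: 270, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 59913, atoms_per_molecule: 3}
  hpg27_mix:
    notes: HPG, 27 chains, four-terpenoid mixture (27:270:26:22:10)
    species:
      - {name: HPG, role: polymer, molecules: 27, atoms_per_molecule: 210}
      - {name: carvacrol, role: terpenoid, molecules: 270, atoms_per_molecule: 25}
      - {name: p-cymene, role: terpenoid, molecules: 26, atoms_per_molecule: 24}
      - {name: gamma-terpinene, role: terpenoid, molecules: 22, atoms_per_molecule: 26}
      - {name: thymol, role: terpenoid, molecules: 10, atoms_per_molecule: 25}
      - {name: water, role: water, molecules: 59913, atoms_per_molecule: 3}
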