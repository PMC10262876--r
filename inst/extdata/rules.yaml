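# Fortification-level decision rules by estimated per-capita intake of the
# flour vehicle (g/day). Bands are half-open [min, max); `.inf` marks the
# open top band. Levels follow WHO guidance on wheat-flour fortification;
# edit or extend for other nutrients or updated guidance.
folic_acid:
  bands:
    - {min: 0, max: 75, level_mg_per_kg: 5.0}
    - {min: 75, max: 150, level_mg_per_kg: 2.6}
    - {min: 150, max: 300, level_mg_per_kg: 1.3}
    - {min: 300, max: .inf, level_mg_per_kg: 1.0}
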