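# Example finite-dose IVPT scenario. Unset keys fall back to the
# hewitt_ivpt_default template and are echoed when loaded.
template: hewitt_ivpt_default
chemical: "4-Tolunitrile"
solvent: water
vehicle_loading_mg_cm2: 10
permeant_fraction: 0.01
area_cm2: 1
donor_height_cm: 1
temperature_c: 32
relative_humidity_pct: 50
duration_h: 24
mode: mechanistic
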