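# Lab-scale batch bioreactor B1 (manure digestion)
bioreactor:
  pH_init: 8.00
  T_C: 35.00
  V_liq: 1.00
  V_gas: 0.10
  p_total: 1.0059
  t_total: 60
feedstock:
  ch: 15.0
  pr: 35.0
  li: 3.0
  inert: 50.0
  Cio: 2.5
  Nio: 2.0
  Pio: 2.6
  Sio_id: 0.1
  Sio_at: 0.5
  NO2: 0.008
  tm:
    Ca: 3.0
    Co: 0.02
    Cr: 0.003
    Cu: 0.01
    Fe: 0.11
    K: 3.2
    Mg: 0.8
    Na: 0.3
    Ni: 0.001
    Pb: 0.0002
    Zn: 0.05
solver:
  dt: 0.01
  method: rk4
  ph_mode: resolve
seed: 1
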