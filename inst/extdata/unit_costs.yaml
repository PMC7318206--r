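adviser_rate: 37.0
trainer_rate: 42.0
demo_kit: 19.35
ec_kit: 19.35
ec_kit_2016: 30.54
extra_liquid: 1.34
info_sheet: 0.09
pharmacy_list: 0.05
lor_print: 0.01
rx_charge: 8.2
session_minutes:
- 30.0
- 30.0
- 20.0
- 20.0
- 20.0
- 20.0
nrt_item_costs:
  patch: 10.5
  gum: 8.4
  lozenge: 12.1
  inhalator: 15.3
  spray: 14.2
  microtab: 9.8
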