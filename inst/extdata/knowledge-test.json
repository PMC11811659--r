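[
  {
    "item": 1,
    "can_walk": true,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 16,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 1
  },
  {
    "item": 2,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 18,
    "cap_refill_s": 1.5,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 2
  },
  {
    "item": 3,
    "can_walk": false,
    "breathing": false,
    "airway_clear_after_reposition": false,
    "respiration_rate": 0,
    "cap_refill_s": 3,
    "radial_pulse_present": false,
    "follows_commands": false,
    "heavy_bleeding": false,
    "key": 4
  },
  {
    "item": 4,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 35,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": true,
    "key": 3
  },
  {
    "item": 5,
    "can_walk": true,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 14,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 1
  },
  {
    "item": 6,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 22,
    "cap_refill_s": 1.9,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 2
  },
  {
    "item": 7,
    "can_walk": false,
    "breathing": false,
    "airway_clear_after_reposition": true,
    "respiration_rate": 0,
    "cap_refill_s": 2.5,
    "radial_pulse_present": false,
    "follows_commands": false,
    "heavy_bleeding": false,
    "key": 3
  },
  {
    "item": 8,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 40,
    "cap_refill_s": 1.5,
    "radial_pulse_present": true,
    "follows_commands": false,
    "heavy_bleeding": true,
    "key": 3
  },
  {
    "item": 9,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 17,
    "cap_refill_s": 1,
    "radial_pulse_present": false,
    "follows_commands": true,
    "heavy_bleeding": true,
    "key": 3
  },
  {
    "item": 10,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 24,
    "cap_refill_s": 1.8,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 2
  },
  {
    "item": 11,
    "can_walk": true,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 15,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 1
  },
  {
    "item": 12,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 32,
    "cap_refill_s": 1.2,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 3
  },
  {
    "item": 13,
    "can_walk": false,
    "breathing": false,
    "airway_clear_after_reposition": false,
    "respiration_rate": 0,
    "cap_refill_s": 4,
    "radial_pulse_present": false,
    "follows_commands": false,
    "heavy_bleeding": false,
    "key": 4
  },
  {
    "item": 14,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 20,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 2
  },
  {
    "item": 15,
    "can_walk": true,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 18,
    "cap_refill_s": 1.1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 1
  },
  {
    "item": 16,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 19,
    "cap_refill_s": 1.7,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": true,
    "key": 2
  },
  {
    "item": 17,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 36,
    "cap_refill_s": 1.4,
    "radial_pulse_present": true,
    "follows_commands": false,
    "heavy_bleeding": true,
    "key": 3
  },
  {
    "item": 18,
    "can_walk": false,
    "breathing": false,
    "airway_clear_after_reposition": false,
    "respiration_rate": 0,
    "cap_refill_s": 3.5,
    "radial_pulse_present": false,
    "follows_commands": false,
    "heavy_bleeding": false,
    "key": 4
  },
  {
    "item": 19,
    "can_walk": true,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 16,
    "cap_refill_s": 1,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 1
  },
  {
    "item": 20,
    "can_walk": false,
    "breathing": true,
    "airway_clear_after_reposition": true,
    "respiration_rate": 21,
    "cap_refill_s": 1.6,
    "radial_pulse_present": true,
    "follows_commands": true,
    "heavy_bleeding": false,
    "key": 2
  }
]
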