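{
  "id": "3",
  "label": "car and SUV in a busy inner-city area",
  "declared_counts": {
    "green": 1,
    "yellow": 3,
    "red": 2,
    "black": 0
  },
  "mean_duration_min": 5.06,
  "sd_duration_min": 1.59,
  "roster": [
    {
      "patient_id": "p01",
      "true_color": "green",
      "assessment": {
        "can_walk": true,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 17,
        "cap_refill_s": 1,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": false
      }
    },
    {
      "patient_id": "p02",
      "true_color": "yellow",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 22,
        "cap_refill_s": 1.4,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": true
      }
    },
    {
      "patient_id": "p03",
      "true_color": "yellow",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 24,
        "cap_refill_s": 1,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": false
      }
    },
    {
      "patient_id": "p04",
      "true_color": "yellow",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 18,
        "cap_refill_s": 1.2,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": true
      }
    },
    {
      "patient_id": "p05",
      "true_color": "red",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 24,
        "cap_refill_s": 3.2,
        "radial_pulse_present": false,
        "follows_commands": true,
        "heavy_bleeding": true
      }
    },
    {
      "patient_id": "p06",
      "true_color": "red",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 22,
        "cap_refill_s": 1.8,
        "radial_pulse_present": true,
        "follows_commands": false,
        "heavy_bleeding": false
      }
    }
  ],
  "aois": [
    {
      "aoi_id": "patients_a",
      "category": "patients",
      "vertices": [
        {
          "x": -75,
          "y": -12
        },
        {
          "x": -47,
          "y": -12
        },
        {
          "x": -47,
          "y": 10
        },
        {
          "x": -75,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "patients_b",
      "category": "patients",
      "vertices": [
        {
          "x": 0,
          "y": -15
        },
        {
          "x": 28,
          "y": -15
        },
        {
          "x": 28,
          "y": 7
        },
        {
          "x": 0,
          "y": 7
        }
      ]
    },
    {
      "aoi_id": "safety_crowd",
      "category": "safety",
      "vertices": [
        {
          "x": -160,
          "y": -8
        },
        {
          "x": -132,
          "y": -8
        },
        {
          "x": -132,
          "y": 8
        },
        {
          "x": -160,
          "y": 8
        }
      ]
    },
    {
      "aoi_id": "vi_zone_1",
      "category": "vehicle_impact",
      "vertices": [
        {
          "x": 40,
          "y": -2
        },
        {
          "x": 60,
          "y": -2
        },
        {
          "x": 60,
          "y": 14
        },
        {
          "x": 40,
          "y": 14
        }
      ]
    },
    {
      "aoi_id": "vi_zone_2",
      "category": "vehicle_impact",
      "vertices": [
        {
          "x": 70,
          "y": -2
        },
        {
          "x": 90,
          "y": -2
        },
        {
          "x": 90,
          "y": 14
        },
        {
          "x": 70,
          "y": 14
        }
      ]
    },
    {
      "aoi_id": "distractor_filming",
      "category": "distractor",
      "vertices": [
        {
          "x": 120,
          "y": -5
        },
        {
          "x": 136,
          "y": -5
        },
        {
          "x": 136,
          "y": 17
        },
        {
          "x": 120,
          "y": 17
        }
      ]
    }
  ]
}
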