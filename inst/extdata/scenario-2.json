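{
  "id": "2",
  "label": "car, van and motorcyclist on a motorway",
  "declared_counts": {
    "green": 1,
    "yellow": 3,
    "red": 1,
    "black": 0
  },
  "mean_duration_min": 5.33,
  "sd_duration_min": 1.37,
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
    }
  ],
  "aois": [
    {
      "aoi_id": "patients_a",
      "category": "patients",
      "vertices": [
        {
          "x": -70,
          "y": -12
        },
        {
          "x": -42,
          "y": -12
        },
        {
          "x": -42,
          "y": 8
        },
        {
          "x": -70,
          "y": 8
        }
      ]
    },
    {
      "aoi_id": "patients_b",
      "category": "patients",
      "vertices": [
        {
          "x": 5,
          "y": -12
        },
        {
          "x": 35,
          "y": -12
        },
        {
          "x": 35,
          "y": 8
        },
        {
          "x": 5,
          "y": 8
        }
      ]
    },
    {
      "aoi_id": "safety_traffic",
      "category": "safety",
      "vertices": [
        {
          "x": -150,
          "y": -5
        },
        {
          "x": -120,
          "y": -5
        },
        {
          "x": -120,
          "y": 10
        },
        {
          "x": -150,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "vi_zone",
      "category": "vehicle_impact",
      "vertices": [
        {
          "x": 50,
          "y": 0
        },
        {
          "x": 75,
          "y": 0
        },
        {
          "x": 75,
          "y": 18
        },
        {
          "x": 50,
          "y": 18
        }
      ]
    }
  ]
}
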