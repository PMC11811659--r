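{
  "id": "1",
  "label": "two-car accident on a countryside road",
  "declared_counts": {
    "green": 3,
    "yellow": 1,
    "red": 0,
    "black": 0
  },
  "mean_duration_min": 3.32,
  "sd_duration_min": 1.03,
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
      "true_color": "green",
      "assessment": {
        "can_walk": true,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 18,
        "cap_refill_s": 1,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": false
      }
    },
    {
      "patient_id": "p03",
      "true_color": "green",
      "assessment": {
        "can_walk": true,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 16,
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
    }
  ],
  "aois": [
    {
      "aoi_id": "patients_a",
      "category": "patients",
      "vertices": [
        {
          "x": -60,
          "y": -10
        },
        {
          "x": -35,
          "y": -10
        },
        {
          "x": -35,
          "y": 10
        },
        {
          "x": -60,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "patients_b",
      "category": "patients",
      "vertices": [
        {
          "x": 10,
          "y": -10
        },
        {
          "x": 35,
          "y": -10
        },
        {
          "x": 35,
          "y": 10
        },
        {
          "x": 10,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "safety_oil",
      "category": "safety",
      "vertices": [
        {
          "x": -20,
          "y": -30
        },
        {
          "x": -2,
          "y": -30
        },
        {
          "x": -2,
          "y": -18
        },
        {
          "x": -20,
          "y": -18
        }
      ]
    },
    {
      "aoi_id": "vi_zone",
      "category": "vehicle_impact",
      "vertices": [
        {
          "x": 45,
          "y": 5
        },
        {
          "x": 67,
          "y": 5
        },
        {
          "x": 67,
          "y": 23
        },
        {
          "x": 45,
          "y": 23
        }
      ]
    }
  ]
}
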