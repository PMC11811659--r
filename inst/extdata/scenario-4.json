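{
  "id": "4",
  "label": "expressway accident with three cars and a van",
  "declared_counts": {
    "green": 1,
    "yellow": 3,
    "red": 3,
    "black": 1
  },
  "mean_duration_min": 7.28,
  "sd_duration_min": 1.97,
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
    },
    {
      "patient_id": "p07",
      "true_color": "red",
      "assessment": {
        "can_walk": false,
        "breathing": true,
        "airway_clear_after_reposition": true,
        "respiration_rate": 37,
        "cap_refill_s": 1.5,
        "radial_pulse_present": true,
        "follows_commands": true,
        "heavy_bleeding": false
      }
    },
    {
      "patient_id": "p08",
      "true_color": "black",
      "assessment": {
        "can_walk": false,
        "breathing": false,
        "airway_clear_after_reposition": false,
        "respiration_rate": 0,
        "cap_refill_s": 5,
        "radial_pulse_present": false,
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
          "x": -80,
          "y": -14
        },
        {
          "x": -50,
          "y": -14
        },
        {
          "x": -50,
          "y": 10
        },
        {
          "x": -80,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "patients_b",
      "category": "patients",
      "vertices": [
        {
          "x": -10,
          "y": -14
        },
        {
          "x": 20,
          "y": -14
        },
        {
          "x": 20,
          "y": 10
        },
        {
          "x": -10,
          "y": 10
        }
      ]
    },
    {
      "aoi_id": "safety_traffic",
      "category": "safety",
      "vertices": [
        {
          "x": -155,
          "y": -6
        },
        {
          "x": -125,
          "y": -6
        },
        {
          "x": -125,
          "y": 9
        },
        {
          "x": -155,
          "y": 9
        }
      ]
    },
    {
      "aoi_id": "vi_zone_1",
      "category": "vehicle_impact",
      "vertices": [
        {
          "x": 35,
          "y": -4
        },
        {
          "x": 57,
          "y": -4
        },
        {
          "x": 57,
          "y": 14
        },
        {
          "x": 35,
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
          "y": -4
        },
        {
          "x": 92,
          "y": -4
        },
        {
          "x": 92,
          "y": 14
        },
        {
          "x": 70,
          "y": 14
        }
      ]
    }
  ]
}
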