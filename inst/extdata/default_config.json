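{
  "imu_rate_hz": 100,
  "alpha": 0.98,
  "seed": 1,
  "duty_ceiling_pct": 100,
  "stimulation": [
    {
      "channel_id": 1,
      "frequency_hz": 50,
      "pulse_duration_us": 200,
      "amplitude_duty_pct": 5
    },
    {
      "channel_id": 2,
      "frequency_hz": 50,
      "pulse_duration_us": 200,
      "amplitude_duty_pct": 5
    },
    {
      "channel_id": 3,
      "frequency_hz": 50,
      "pulse_duration_us": 200,
      "amplitude_duty_pct": 5
    },
    {
      "channel_id": 4,
      "frequency_hz": 50,
      "pulse_duration_us": 200,
      "amplitude_duty_pct": 5
    }
  ],
  "pid_sagittal": {
    "kp": 8.2,
    "ki": 3.8,
    "kd": 0,
    "u_min": -14,
    "u_max": 10
  },
  "pid_frontal": {
    "kp": 8.1,
    "ki": 3.2,
    "kd": 0,
    "u_min": -12,
    "u_max": 14
  },
  "pairs": {
    "sagittal": {
      "agonist": 1,
      "antagonist": 2
    },
    "frontal": {
      "agonist": 3,
      "antagonist": 4
    }
  },
  "profile": [
    {
      "label": "neutral",
      "start_s": 0,
      "end_s": 10,
      "sagittal_ref_deg": 0,
      "frontal_ref_deg": 0
    },
    {
      "label": "inversion",
      "start_s": 10,
      "end_s": 20,
      "sagittal_ref_deg": 0,
      "frontal_ref_deg": 20
    },
    {
      "label": "eversion",
      "start_s": 20,
      "end_s": 25,
      "sagittal_ref_deg": 0,
      "frontal_ref_deg": -5
    },
    {
      "label": "neutral",
      "start_s": 25,
      "end_s": 35,
      "sagittal_ref_deg": 0,
      "frontal_ref_deg": 0
    },
    {
      "label": "dorsiflexion",
      "start_s": 35,
      "end_s": 45,
      "sagittal_ref_deg": 20,
      "frontal_ref_deg": 0
    },
    {
      "label": "plantar_flexion",
      "start_s": 45,
      "end_s": 55,
      "sagittal_ref_deg": -20,
      "frontal_ref_deg": 0
    },
    {
      "label": "neutral",
      "start_s": 55,
      "end_s": 60,
      "sagittal_ref_deg": 0,
      "frontal_ref_deg": 0
    }
  ]
}
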