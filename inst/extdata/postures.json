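{
  "_comment": "Synthetic working-posture profiles: parameterised reconstructions of twelve common standing/stooping/kneeling/lifting tasks from ergonomic assessment worksheets. Angles in degrees; knee/elbow angles are flexion from straight; trunk/neck/upper-arm angles are signed flexion (toward the facing direction positive). Edit freely: these are representative profiles, not measured replicas.",
  "postures": [
    {
      "name": "upright_standing",
      "facing": "left",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": 0, "trunk": 0, "leg_left": 0, "leg_right": 0,
                 "upper_arm_left": 0, "upper_arm_right": 0,
                 "lower_arm_left": 0, "lower_arm_right": 0,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "standing_reach_forward",
      "facing": "right",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": 10, "trunk": 10, "leg_left": 0, "leg_right": 0,
                 "upper_arm_left": 60, "upper_arm_right": 55,
                 "lower_arm_left": 15, "lower_arm_right": 20,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "stoop_lift",
      "facing": "right",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 10, "right": 10},
      "occlude": [],
      "angles": {"neck": 20, "trunk": 70, "leg_left": 5, "leg_right": 10,
                 "upper_arm_left": 10, "upper_arm_right": 10,
                 "lower_arm_left": 20, "lower_arm_right": 25,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "overhead_reach",
      "facing": "left",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": -15, "trunk": -10, "leg_left": 0, "leg_right": 0,
                 "upper_arm_left": 120, "upper_arm_right": 115,
                 "lower_arm_left": 10, "lower_arm_right": 15,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "kneel_work",
      "facing": "right",
      "leg_support": "kneeling",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 30},
      "occlude": [],
      "angles": {"neck": 15, "trunk": 20, "leg_left": 10, "leg_right": 110,
                 "upper_arm_left": 30, "upper_arm_right": 25,
                 "lower_arm_left": 60, "lower_arm_right": 65,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "step_up",
      "facing": "right",
      "leg_support": "unilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 45},
      "occlude": [],
      "angles": {"neck": 5, "trunk": 15, "leg_left": 0, "leg_right": 45,
                 "upper_arm_left": 20, "upper_arm_right": 25,
                 "lower_arm_left": 40, "lower_arm_right": 45,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "twist_reach",
      "facing": "left",
      "leg_support": "bilateral",
      "twist_trunk": true, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": 10, "trunk": 25, "leg_left": 5, "leg_right": 5,
                 "upper_arm_left": 45, "upper_arm_right": 40,
                 "lower_arm_left": 30, "lower_arm_right": 35,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "twist_inspect",
      "facing": "left",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": true, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": 20, "trunk": 5, "leg_left": 0, "leg_right": 0,
                 "upper_arm_left": 10, "upper_arm_right": 10,
                 "lower_arm_left": 70, "lower_arm_right": 75,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "deep_stoop",
      "facing": "right",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 15, "right": 15},
      "occlude": [],
      "angles": {"neck": 25, "trunk": 85, "leg_left": 20, "leg_right": 25,
                 "upper_arm_left": 15, "upper_arm_right": 18,
                 "lower_arm_left": 10, "lower_arm_right": 12,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "carry_box",
      "facing": "right",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": ["left_wrist"],
      "angles": {"neck": 5, "trunk": 10, "leg_left": 0, "leg_right": 5,
                 "upper_arm_left": 30, "upper_arm_right": 35,
                 "lower_arm_left": 80, "lower_arm_right": 85,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "shrug_carry",
      "facing": "left",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": true,
      "hip_flexion": {"left": 0, "right": 0},
      "occlude": [],
      "angles": {"neck": 10, "trunk": 5, "leg_left": 0, "leg_right": 0,
                 "upper_arm_left": 30, "upper_arm_right": 28,
                 "lower_arm_left": 90, "lower_arm_right": 85,
                 "wrist_left": 0, "wrist_right": 0}
    },
    {
      "name": "crouch",
      "facing": "right",
      "leg_support": "bilateral",
      "twist_trunk": false, "twist_neck": false, "shoulders_raised": false,
      "hip_flexion": {"left": 60, "right": 60},
      "occlude": [],
      "angles": {"neck": 20, "trunk": 40, "leg_left": 70, "leg_right": 75,
                 "upper_arm_left": 40, "upper_arm_right": 45,
                 "lower_arm_left": 50, "lower_arm_right": 55,
                 "wrist_left": 0, "wrist_right": 0}
    }
  ]
}
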