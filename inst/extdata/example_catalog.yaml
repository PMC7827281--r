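format: exertrack_catalog
version: 1
exercises:
- id: shoulder_01
  name: shoulder abduction left 70deg
  family: shoulder
  movement: abduction
  side: left
  template: concentric_angle
  controlled_joints:
  - SHOULDER_LEFT
  - ELBOW_LEFT
  - WRIST_LEFT
  target: 70.0
  target_unit: degrees
  repetitions: 12.0
  series: 3
  tolerance: elderly
- id: shoulder_03
  name: shoulder abduction left 110deg
  family: shoulder
  movement: abduction
  side: left
  template: concentric_angle
  controlled_joints:
  - SHOULDER_LEFT
  - ELBOW_LEFT
  - WRIST_LEFT
  target: 110.0
  target_unit: degrees
  repetitions: 12.0
  series: 3
  tolerance: elderly
- id: shoulder_21
  name: shoulder rotation left 45deg
  family: shoulder
  movement: rotation
  side: left
  template: concentric_angle
  controlled_joints:
  - SHOULDER_LEFT
  - ELBOW_LEFT
  - WRIST_LEFT
  target: 45.0
  target_unit: degrees
  repetitions: 10.0
  series: 3
  tolerance: elderly
- id: knee_01
  name: knee squat both 160deg
  family: knee
  movement: squat
  side: both
  template: posture_constrained_squat
  controlled_joints:
  - HIP_LEFT
  - KNEE_LEFT
  - ANKLE_LEFT
  - FOOT_LEFT
  - HIP_RIGHT
  - KNEE_RIGHT
  - ANKLE_RIGHT
  - FOOT_RIGHT
  target: 160.0
  target_unit: degrees
  repetitions: 10.0
  series: 3
  tolerance: elderly
- id: knee_11
  name: knee extension left 150deg
  family: knee
  movement: extension
  side: left
  template: concentric_angle
  controlled_joints:
  - HIP_LEFT
  - KNEE_LEFT
  - ANKLE_LEFT
  target: 150.0
  target_unit: degrees
  repetitions: 12.0
  series: 3
  tolerance: elderly
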