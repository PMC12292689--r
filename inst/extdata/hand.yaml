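# Example key-finger-exoskeleton configuration: index finger, three phalanges.
chain:
  lengths: [0.045, 0.025, 0.018]   # m, proximal -> distal
  theta: [0.3, 0.3, 0.2]           # rad
  theta_dot: [0.0, 0.0, 0.0]
key:
  ks: 100      # N/m
  bs: 0.5      # N s/m
  travel: 0.01
exo:
  kp: 0.8      # N m/rad, expanded to a diagonal gain matrix
  kd: 0.05
  ks: 0.1      # structural stiffness about theta_eq
  me: [0.0002, 0.0001, 0.00005]   # actuator/linkage inertia reflected at the joints
  ce: 0.02
  theta_eq: [0.3, 0.3, 0.2]
  theta_d: [0.6, 0.5, 0.3]
muscles:
  - {fmax: 100, l0: 0.25, r0: 0.011, vmax: 0.5, alpha: 0.1}
  - {fmax: 60,  l0: 0.25, r0: 0.008, vmax: 0.5, alpha: 0.1}
  - {fmax: 30,  l0: 0.25, r0: 0.005, vmax: 0.5, alpha: 0.1}
contact_height: 0.045   # fingertip height of key contact, m
d_joint: [0.0225, 0.0125, 0.009]
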