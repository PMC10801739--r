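# Default passive-element parameters (version 1).
#
# Ligament stiffness is expressed in N per unit strain with a quadratic-toe
# tension-only law; intervertebral disc bushings use tabulated nonlinear
# moment-angle (Nm vs deg) and force-displacement (N vs mm) characteristics
# interpolated with monotone cubics; facet contacts are frictionless
# point-on-plane penalties with a C1 force onset. Values are typical lumbar
# magnitudes from the in vitro / in silico literature; the global `scale`
# multipliers are set by the range-of-motion calibration against the
# published flexion-extension validation corridor. Damping coefficients are
# small positive values for numerical settling, not physiologic claims.
version: 1
scale:
  ligament: 1.0
  ivd_rot: 1.0
ligaments:
  ALL:  {k: 1300, toe_strain: 0.05, toe_shape: 2, slack_ratio: 1.0}
  PLL:  {k: 800,  toe_strain: 0.05, toe_shape: 2, slack_ratio: 1.0}
  LF:   {k: 650,  toe_strain: 0.04, toe_shape: 2, slack_ratio: 1.0}
  ISL:  {k: 600,  toe_strain: 0.04, toe_shape: 2, slack_ratio: 1.0}
  SSL:  {k: 1000, toe_strain: 0.04, toe_shape: 2, slack_ratio: 1.0}
  ITL:  {k: 600,  toe_strain: 0.05, toe_shape: 2, slack_ratio: 1.0}
  CL:   {k: 800,  toe_strain: 0.04, toe_shape: 2, slack_ratio: 1.0}
ivd:
  rot_damping: [1.5, 1.5, 1.5]      # Nm s/rad about FE, LB, AR
  trans_damping: [1000, 1000, 1500] # N s/m along AP, ML, SI
  curves:
    FE:  # flexion positive, strain-stiffening toward end range
      angle_deg: [-12, -10, -8, -6, -4, -2, -1, 0, 1, 2, 4, 6, 8, 10, 12]
      moment_nm: [-37, -24.5, -14.5, -9.2, -5.0, -2.0, -0.9, 0,
                  0.75, 1.6, 3.9, 7.2, 13.5, 22, 34]
    LB:  # odd-symmetric; lateral bending is stiffer than flexion
      angle_deg: [-12, -10, -8, -6, -4, -2, 0, 2, 4, 6, 8, 10, 12]
      moment_nm: [-52, -36, -24, -15.5, -9, -4, 0, 4, 9, 15.5, 24, 36, 52]
    AR:  # odd-symmetric; axial rotation strongly facet-guarded
      angle_deg: [-6, -5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5, 6]
      moment_nm: [-31, -23, -16, -10.5, -6, -2.5, 0, 2.5, 6, 10.5, 16, 23, 31]
    AP:  # anterior displacement positive
      disp_mm: [-5, -3, -1.5, 0, 1.5, 3, 5]
      force_n: [-980, -520, -230, 0, 230, 520, 980]
    ML:
      disp_mm: [-5, -3, -1.5, 0, 1.5, 3, 5]
      force_n: [-1500, -800, -350, 0, 350, 800, 1500]
    SI:  # compression positive
      disp_mm: [-1.5, -0.75, 0, 1, 2, 3]
      force_n: [-500, -270, 0, 400, 1000, 1800]
facet:
  penalty_stiffness_n_mm: 600
  smoothing_mm: 0.1
  damping_n_s_m: 800
simulation:
  rtol: 1.0e-6
  atol: 1.0e-8       # positions (m) and quaternion components
  atol_vel: 1.0e-5   # velocity states (m/s, rad/s)
  n_out: 101
  duration_s: 3.0
  ramp_fraction: 0.9
  presettle: false          # optionally settle under the preload before t = 0
  settle_duration_s: 1.0
  settle_damp_mult: 4.0
  applied_moment_nm: 7.5
  vertical_force_n: 500
  gravity: false
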