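# Default simplified glenohumeral model.
#
# Frame (scapula-fixed, ISB-style): x anterior, y superior, z lateral.
# The glenohumeral rotation centre sits at the origin; the glenoid plane faces
# it from z = -standoff. Moment-arm polynomials are in t = elevation_gh / 100
# (degrees), metres; they are stand-ins seeded from published anatomical
# moment-arm curves, not a fit to any subject.
schema: glenosim-model/1
joint_center_m: [0.0, 0.0, 0.0]
glenoid:
  ap_diameter_mm: 28.0
  si_diameter_mm: 38.0
  center_m: [0.0, 0.0, -0.025]
  normal: [0.0, 0.0, 1.0]
  si_axis: [0.0, 1.0, 0.0]
rhythm:
  # below threshold all elevation is glenohumeral; above it the glenohumeral
  # joint takes gh_fraction of each additional thoracohumeral degree (2:1
  # glenohumeral-to-scapulothoracic rhythm).
  threshold_deg: 30.0
  gh_fraction: 0.6667
envelope_gh_deg: [0.0, 135.0]
max_moment_arm_m: 0.06
muscles:
  - name: SSP
    fmax_n: 500.0
    r_el_poly_m: [0.023, -0.006]
    plane_pref_deg: 0.0
    plane_sens: 0.3
    r_rot_m: 0.002
    r_plane_m: 0.0
    u0: [0.0, 0.30, -0.95]
    du: [0.0, -0.25, -0.10]
  - name: ISP
    fmax_n: 600.0
    r_el_poly_m: [0.004]
    plane_pref_deg: 0.0
    plane_sens: 0.0
    r_rot_m: 0.022
    r_plane_m: -0.002
    u0: [-0.10, -0.33, -0.94]
    du: [0.0, 0.05, 0.0]
  - name: SSC
    fmax_n: 1000.0
    r_el_poly_m: [0.004]
    plane_pref_deg: 0.0
    plane_sens: 0.0
    r_rot_m: -0.021
    r_plane_m: 0.002
    u0: [0.10, -0.33, -0.94]
    du: [0.0, 0.05, 0.0]
  - name: Tm
    fmax_n: 250.0
    r_el_poly_m: [-0.003]
    plane_pref_deg: 0.0
    plane_sens: 0.0
    r_rot_m: 0.020
    r_plane_m: -0.002
    u0: [-0.05, -0.45, -0.89]
    du: [0.0, 0.0, -0.05]
  - name: AD
    fmax_n: 800.0
    r_el_poly_m: [0.015, 0.015]
    plane_pref_deg: 90.0
    plane_sens: 0.8
    r_rot_m: -0.004
    r_plane_m: 0.020
    u0: [0.25, 0.85, -0.45]
    du: [0.0, -0.35, -0.35]
  - name: MD
    fmax_n: 1200.0
    r_el_poly_m: [0.016, 0.016]
    plane_pref_deg: 0.0
    plane_sens: 0.25
    r_rot_m: 0.0
    r_plane_m: 0.0
    u0: [0.0, 0.92, -0.39]
    du: [0.0, -0.40, -0.40]
  - name: PD
    fmax_n: 800.0
    r_el_poly_m: [0.010, 0.010]
    plane_pref_deg: -45.0
    plane_sens: 0.5
    r_rot_m: 0.005
    r_plane_m: -0.020
    u0: [-0.25, 0.80, -0.54]
    du: [0.0, -0.30, -0.30]
  - name: LHB
    fmax_n: 300.0
    r_el_poly_m: [0.006]
    plane_pref_deg: 90.0
    plane_sens: 0.4
    r_rot_m: 0.0
    r_plane_m: 0.0
    u0: [0.05, -0.10, -0.99]
    du: [0.0, 0.0, 0.0]
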