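# Generic-adult anthropometry for the four-link sagittal model (synthetic
# fixture). Per-link values follow standard anthropometric proportion tables
# (segment mass fractions and radii of gyration for a generic adult), with
# both legs lumped into the single modeled limb and the pelvis lumped into
# the HAT (head-arms-torso) segment. Totals are constrained to a 75.2 kg
# body mass and a 0.826 m leg length (shank + thigh). These are NOT
# subject-specific values; supply your own file to override.
#
# Units: mass_kg (kg), length_m / ref_length_m / com_offset_m / com_m (m),
# inertia_kgm2 (kg m^2, about the segment COM, z axis).
# com_offset_m is measured from the link's proximal chain joint
# (shank: ankle; thigh: knee; hat: hip). The foot COM is given as an [x, y]
# point in the foot frame (origin O on the ground below the ankle).
model_name: generic_adult_synthetic
links:
  foot:
    mass_kg: 2.181           # 2 x 0.0145 body-mass fraction
    inertia_kgm2: 0.0260
    com_m: [0.055, 0.035]
  shank:
    mass_kg: 6.994           # 2 x 0.0465 body-mass fraction
    length_m: 0.400
    com_offset_m: 0.2268     # 0.567 of length from the ankle
    inertia_kgm2: 0.1021
  thigh:
    mass_kg: 15.040          # 2 x 0.100 body-mass fraction
    length_m: 0.426
    com_offset_m: 0.2415     # 0.567 of length from the knee
    inertia_kgm2: 0.2848
  hat:
    mass_kg: 50.985          # remainder; 0.678 body-mass fraction
    ref_length_m: 0.550      # hip to HAT COM reference line
    com_offset_m: 0.320
    inertia_kgm2: 3.794
foot_triangle:
  # posterior calcaneus C, distal toe T on the ground line; ankle A directly
  # above the origin O (OA perpendicular to CT)
  C: [-0.060, 0.0]
  T: [0.190, 0.0]
  A: [0.0, 0.080]
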