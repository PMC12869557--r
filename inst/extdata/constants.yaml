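# Resolved physical constants for the intra-organoid delivery platform.
# Units: lengths um unless suffixed, permeability m^2, diffusivity um^2/s,
# concentration uM, pressure Pa, density kg/m^3, viscosity Pa.s, rates 1/s.
# Any entry can be overridden per run via of_constants(overrides = ...).
materials:
  membrane:
    porosity: 0.094
    permeability_m2: 1.2e-16
    tortuosity: 1
  organoid:
    porosity: 0.2
    permeability_m2: 3.75e-15
    tortuosity: 1
  agarose:
    porosity: 0.99
    permeability_m2: 8.2e-16
    tortuosity: 1
fluid:
  density_kg_m3: 997.0
  viscosity_Pa_s: 0.0010016
solutes:
  magnevist:
    diffusivity_um2_s: 450.0
    c_source_uM: 5600.0        # 5.6 mM contrast reagent
  srb:
    diffusivity_um2_s: 470.0
    c_source_uM: 10.0          # 10 uM sulforhodamine B
  iohexol:
    diffusivity_um2_s: 250.0
    c_source_uM: 365340.0      # 300 mg/mL at 821.14 g/mol
saturation:
  s0: 0.075
  ks: 3.7e-5
membrane_geom:
  thickness_um: 10.0
  pore_diameter_nm: 200.0
  pore_density_cm2: 3.0e8
  barrier_thickness_um: 1.0
channel:
  inner_width_r0_um: 20.0
  inner_width_rmax_um: 200.0
  outer_width_r0_um: 60.0
  outer_width_rmax_um: 2000.0
  r_max_mm: 11.7
  depth_um: 10.0
  n_wings: 8
cage:
  # (height z um, diameter um); base diameter is the central bonding region
  anchors:
    - [0, 110]
    - [398, 771]
    - [1480, 339]
    - [2130, 1580]
organoid_geom:
  r0_mm: 1.0
  r0z_mm: 0.98
  r_source_um: 385.5           # half the 771 um maximum cage diameter
phantom_geom:
  length_mm: 5.0
  height_um: 500.0
pressures_Pa:
  magnevist: 690.0
  srb: 510.0
  iohexol: 196.0
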