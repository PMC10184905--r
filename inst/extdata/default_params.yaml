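# Default consortium parameters.
# Units: rates 1/s; concentrations and affinities kg/m^3; lengths um;
# density fg/um^3 (== g/L); diffusion coefficients m^2/s.
cyanobacterium:
  mu_max: 1.89e-5
  yield_Y: 0.55
  K_light: 3.5e-4
  K_CO2: 1.38e-4
  maintenance_m: 0.0
  length_min: 2.5
  length_max: 5.0
  diameter: 1.0
  veq_diameter_min: 1.37
  veq_diameter_max: 1.94
  density: 370.0
heterotroph:
  mu_max: 6.71e-5
  yield_Y: 0.43
  K_sucrose: 3.6
  K_O2: 1.0e-3
  maintenance_m: 9.5e-7
  length_min: 1.6
  length_max: 4.0
  diameter: 0.8
  veq_diameter_min: 0.88
  veq_diameter_max: 1.39
  density: 230.0
nutrients:
  light:
    concentration: 1.0e-1
    bc_type: dirichlet
  co2:
    concentration: 3.0e-2
    bc_type: dirichlet
    D: 1.9e-9
  o2:
    concentration: 9.0e-3
    bc_type: dirichlet
    D: 2.3e-9
  sucrose:
    concentration: 1.0e-20
    bc_type: neumann
    D: 5.2e-10
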