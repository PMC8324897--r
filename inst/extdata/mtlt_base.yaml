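# Base configuration: mineralised turkey leg tendon fibre micropillar.
# Every key is optional; missing keys fall back to these same defaults.

composition:
  phi_min: 0.29          # mineral volume fraction (from tissue density 1.64 g/cm^3)
  # rho: 1.64            # alternatively: recompute phi_min from the density
  phi_ncp: 0.14          # non-collagenous proteins incl. bound water
  phi_mc: 0.86           # fibril volume fraction in the fibre
  fibre_diameter_um: 6.08
  fibril_diameter_nm: 224
  packing_density: 0.86
  n_elements: 618        # explicit override (area-ratio formula gives 634)

shearlag:
  E_min: 114             # mineral Young's modulus, GPa
  gamma_min: 25          # mineral platelet aspect ratio
  mu_col: 1.58           # collagen shear modulus, GPa
  gamma_mc: 200          # fibril aspect ratio
  mu_ef: 0.003           # extrafibrillar matrix shear modulus, GPa
  mineral_intrafibrillar: true

plasticity:
  eps_y_mc: 0.028        # intrafibrillar yield strain
  eps_y_ef: 0.012        # extrafibrillar yield strain
  chi_mc: 0.020          # intrafibrillar hardening modulus, GPa
  chi_ef: 0.000003       # extrafibrillar hardening modulus, GPa
  eps_ult_mc: 9.0        # intrafibrillar ultimate plastic strain (100x ef)
  eps_ult_ef: 0.09       # extrafibrillar ultimate plastic strain

distribution:
  family: normal         # normal | skew-normal | degenerate
  cov: 0.15              # coefficient of variation of all varied parameters
  skew: 0
  truncate_at: 0         # reject draws <= truncate_at * mean

recruitment:
  enabled: true
  mu: 0.0215             # sigmoid midpoint (apparent strain)
  beta: 0.00635          # sigmoid shape parameter

protocol:
  peaks: [0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09, 0.10, 0.11, 0.12]
  resolution: 0.0001
  cyclic: true

run:
  seed: 1
  sampling: nested       # nested | direct
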