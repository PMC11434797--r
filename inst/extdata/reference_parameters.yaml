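# Reference fitted parameter set for the coupled tableting reduced-order
# models (10% w/w acetaminophen / 90% w/w microcrystalline cellulose
# dry-granulation formulation; doubly convex D-type tool).
#
# The packing interaction coefficient weight.q1 is stored with its fitted
# (negative) sign; published summaries report its magnitude.
version: 1
formulation:
  true_density_gcc: 1.558
  rho_c_rib: 0.566
tool:
  D_mm: 7.94
  h_mm: 0.3302
weight:
  p4: 0.367
  q1: -6.08
  q2: 7.33
  phi_min: 0.367
  phi_max: 0.631
force:
  rX: 10.0
  rY: 2.39
  b_per_gpa: 61.39
  a_surface:
    variant: 7
    p1: 18.50
    p4: 0.765
    q1: 27.69
  rho_c_surface:
    variant: 7
    p1: 8.73
    p4: 0.33
    q1: 21.38
recovery:
  rX: 1.0
  rY: 1.0
  n_exp: 0.472
  eps0_surface:
    variant: 4
    p1: 5.04
    p2: 0.243
    p4: 0.597
    q1: 18.78
    q2: 16.10
  rho_c_eps_surface:
    variant: 9
    p4: 0.334
strength:
  rX: 8.26
  rZ: 1.98
  sigma0_surface:
    variant: 1
    p1: 0.33
    p2: 124.23
    p3: 0.18
    p4: 5.90
    q1: 1.79
    q2: 8.90
    q3: 0.04
  rho_c_sigma_surface:
    variant: 1
    p1: 50.92
    p2: 14.82
    p3: 0.02
    p4: 0.51
    q1: 79.66
    q2: 41.28
    q3: 0.02
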