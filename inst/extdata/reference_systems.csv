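system,temperature_K,isotope,bond_label,wavenumber_cm1,d_corrected_A,sigma_d_A,d_preconversion_A,provenance
free H2O,,H2O,OH,3706.491,0.9578,0.0001,,equilibrium length from rotational-level fitting; wavenumber is mean of gas-phase v1 and v3
ice Ih,123,HOD,OH,3279,1.014,0.0011,,decoupled HOD Raman peak; +0.008 A thermal correction; two site lengths averaged
ice II,110,D2O,OH-long,3194,1.102,0.021,,longest bond only; isotropic-B thermal correction; D-to-H +3%
ice VI,,D2O,OH-net1,3329,1.026,0.049,0.996,first octahedral network; isotropic-B thermal correction; D-to-H +3%
ice VI,,D2O,OH-net2,3390,0.993,0.028,0.961,second network multiplicity-weighted mean; isotropic-B correction; printed D-to-H value retained (0.961 x 1.03 = 0.990)
ice VIII,10,D2O,OH,3427.9,1.01,0.009,0.981,mean of three coupled normal modes; isotropic-B correction; D-to-H +3%
ice IX,100,D2O,OH-major,3160.4,1.012,0.004,0.983,major proton site only; source-corrected length; D-to-H +3%
ice XVII,,D2O,OH-1,3106.3,1.075,0.007,1.044,isotropic-B thermal correction; D-to-H +3%
ice XVII,,D2O,OH-2,3231.8,1.049,0.004,1.018,isotropic-B thermal correction; D-to-H +3%
gypsum,320,D2O,OH-A,3406,1.014,0.006,0.984,intralayer O-H_A; isotropic-B correction; D-to-H +3%
gypsum,320,D2O,OH-B,3484,0.995,0.004,0.966,interlayer O-H_B; isotropic-B correction; D-to-H +3%
Li2SO4.H2O,,H2O,OH-1,3439,1.004,0.003,,source-corrected length
Li2SO4.H2O,,H2O,OH-2,3480,0.997,0.002,,source-corrected length
CuSO4.5H2O,,H2O,OH-1,3360,1.005,0.005,,non-coordinated water only; anisotropic-beta correction
CuSO4.5H2O,,H2O,OH-2,3477,0.951,0.011,,non-coordinated water only; anisotropic-beta correction
Ba(ClO3)2.H2O,90,H2O,OH,3547,0.958,0.011,,single corrected length; wavenumber is mean of v1 (3512) and v3 (3582)
LiClO4.3H2O,,H2O,OH,3553,0.993,0.004,,mean of three refinement series; correction included in refinement
BaCl2.2H2O,,H2O,OH-1,3456,1.0359,0.003,,anisotropic-beta correction; four uncoupled modes
BaCl2.2H2O,,H2O,OH-2,3352,1.0364,0.003,,anisotropic-beta correction; four uncoupled modes
BaCl2.2H2O,,H2O,OH-3,3318,1.0717,0.003,,anisotropic-beta correction; four uncoupled modes
BaCl2.2H2O,,H2O,OH-4,3303,1.077,0.004,,anisotropic-beta correction; four uncoupled modes
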