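# Worked example: three-tiered food web (chlorophenol / phenol / hydrogen
# community in COD units), single operating point.
#
# The operating point D = 0.1 1/d, S1_in = 5 kgCOD/m3 yields four nonnegative
# fixed points (total washout; two partial steady states with X3 washed out;
# three-species coexistence) and is bistable between total washout and
# coexistence. KS3c (the secondary-substrate affinity of the chlorophenol
# degrader for hydrogen) is taken from the source model of this parameter
# set, 1.0e-6 kgCOD/m3.
motif: three_species_food_web
analysis: single_point
units: COD
parameters:
  D: 0.1          # dilution rate, 1/d
  S1_in: 5.0      # chlorophenol inflow, kgCOD/m3
  S2_in: 0.0      # phenol inflow
  S3_in: 0.0      # hydrogen inflow
  km1: 29.12      # max specific uptake rates, kgCOD_S/kgCOD_X/d
  KS1: 5.2e-5     # half-saturation constants, kgCOD/m3
  Y1: 0.019       # yields, kgCOD_X/kgCOD_S
  kdec1: 0.02     # decay rates, 1/d
  km2: 26.0
  KS2: 0.302
  Y2: 0.04
  kdec2: 0.02
  km3: 35.0
  KS3: 2.5e-5
  Y3: 0.06
  kdec3: 0.02
  Ki3: 3.5e-6     # hydrogen inhibition constant on the phenol degrader
  KS3c: 1.0e-6    # hydrogen affinity of the chlorophenol degrader
  gamma0: 1.0769  # stoichiometric transfer fractions
  gamma1: 0.1429
  gamma2: 0.0769
initial_conditions: 0.1
solver:
  method: stiff
  atol: 1.0e-6
  rtol: 1.0e-3
  t_end: 100
fixed_points:
  n_starts: 200
  seed: 1729
  spectrum: direct
seed: 1729
output_dir: motifsim_out
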