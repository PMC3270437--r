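# Model constants for the lipid-basis PBTK / CYP induction model.
# Every section is optional; omitted keys use the package defaults
# (shown here).

physiology:
  reference_body_weight: 225      # g
  cardiac_output: 4980            # mL blood/h
  tissue_flows:                   # mL blood/h
    fat: 448
    liver: 1245
    rapid: 2540
    poor: 747
  tissue_volumes:                 # mL
    blood: 20.0
    fat: 17.5
    liver: 10.0
    rapid: 12.5
    poor: 167.5

lipid_content:
  blood_nle_ratio: 0.0019         # mL NLE / mL blood; 9.45/4980 is the
                                  # back-calculated alternative

congeners:
  v0:                             # basal clearance, mL/h/kg^0.75
    "118": 0.038
    "138": 0.026
    "153": 0.025
    "170": 0.029
    "180": 0.035
    "187": 0.017

cyp:
  ke: 0.04                        # 1/h
  k0: 0.004                       # nmol/h/g protein
  F_1A: 0.045                     # per ug/mL NLE
  F_2B: 0.0025

solver:
  h0: 0.01                        # h, first step after a dose event
  hmax: 3                         # h, ceiling of the step ladder
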