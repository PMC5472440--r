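# nucleoslide parameter presets (version 1)
#
# Simulator rate-law parameters per complex variant, protomer species
# attributes for the dimer-mixture model, cooperative-binding presets and
# dimer-activity (rate-titration) presets. Concentration units are embedded
# per preset. Values are package defaults; functions accept overrides.
version: 1

simulator:
  WT:
    k_step0: 2.0        # bp/s maximal coupled stepping rate
    s_sense: 50         # bp flank-sensing midpoint
    sense_width: 4      # bp logistic softness of the sensing threshold
    k_atp: 2.2          # 1/s ATP turnover per active nucleosome-bound motor
    p_arrest: 0.2       # arrest probability per well crossing once both flanks sensed
    arrest_sigma: 0.5   # sensing level both flanks need for arrest eligibility
    well_period: 10     # bp spacing of preferred positions
    well_depth: 1.2     # dimensionless landscape bias (well escape slowed e^-depth)
    k_leak: 0.0         # 1/s undirected flank-independent stepping
  EA:                   # dead motor: dimer species flags carry the phenotype
    k_step0: 2.0
    s_sense: 50
    sense_width: 4
    k_atp: 2.2
    p_arrest: 0.2
    arrest_sigma: 0.5
    well_period: 10
    well_depth: 1.2
    k_leak: 0.0
  WTdCTD:               # CTD truncation: shorter sensing, 5x slower stepping,
    k_step0: 0.4        # 2x ATPase, leaky undirected stepping
    s_sense: 35
    sense_width: 4
    k_atp: 4.4
    p_arrest: 0.2
    arrest_sigma: 0.2
    well_period: 10
    well_depth: 1.2
    k_leak: 0.05
  EAdCTD:
    k_step0: 0.4
    s_sense: 35
    sense_width: 4
    k_atp: 4.4
    p_arrest: 0.2
    arrest_sigma: 0.2
    well_period: 10
    well_depth: 1.2
    k_leak: 0.05

species:
  WT:     {motor_active: true,  ctd_present: true}
  EA:     {motor_active: false, ctd_present: true}
  WTdCTD: {motor_active: true,  ctd_present: false}
  EAdCTD: {motor_active: false, ctd_present: false}

binding:
  CTD_DNA:                    # isolated CTD vs 50 bp duplex DNA
    K_half: 1.0
    h: 1.8
    F_min: 0.0
    F_max: 1.0
    unit: uM
    ligand_conc: 0.05         # 50 nM duplex
  WT_nucleosome:              # order-of-magnitude placeholder K_1/2
    K_half: 50
    h: 2.0
    F_min: 0.0
    F_max: 1.0
    unit: nM
    ligand_conc: 20
  dCTD_nucleosome:            # cooperativity of binding lost without the CTD
    K_half: 50
    h: 1.0
    F_min: 0.0
    F_max: 1.0
    unit: nM
    ligand_conc: 20

activity:                     # allosteric sigmoidal rate-titration presets,
  WT:                         # 100 nM nucleosome, concentrations in nM
    sliding: {V_max: 1000, K_half: 100, h: 1.9, unit: nM}   # FU/s
    atpase:  {V_max: 0.44, K_half: 100, h: 1.3, unit: nM}   # uM ATP/s
    basal_atpase_slope: 2.0e-4                               # uM ATP/s per nM protein
  dCTD:
    sliding: {V_max: 200, K_half: 100, h: 1.9, unit: nM}    # 5-fold lower
    atpase:  {V_max: 0.88, K_half: 100, h: 1.3, unit: nM}   # 2-fold higher
    basal_atpase_slope: 2.0e-4                               # unchanged basal rate

stoichiometry:
  default:
    ratio: 2.0
    ligand_conc: 500          # nM nucleosome, saturation design
    unit: nM
    Y1: 0.0
    S1: 1.0                   # FU per nM below the breakpoint
    S2: 0.02                  # FU per nM above it
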