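# Default temperature responses of Aedes aegypti vital rates.
#
# Development and gonotrophic-cycle rates use the Sharpe & DeMichele
# enthalpy (Schoolfield) model; constants follow the AedesBA lineage
# (Otero et al. 2006, after Focks et al. 1993).  deltaH_* are in
# cal/mol, T_half in Kelvin, rho25 in 1/day at the 298 K reference.
# Setting deltaH_H to 0 disables the high-temperature inhibition term.
#
# Mortality baselines (1/day) come from the same lineage.  The high- and
# low-temperature branches are continuous threshold-exponential
# responses; their response constants are package defaults (weakly
# constrained in equatorial climates, where both branches are nearly
# inert).  Thresholds in degrees C.
#
# Water-temperature regressions map each component of the air triple to
# the container-water triple as intercept + slope * T_air + sun * s,
# where s is the average sun-exposure fraction of containers.
n_eggs_per_cycle: 63
sun_exposure: 0.10
development:
  egg:    {rho25: 0.24,   deltaH_A: 10798.0, deltaH_H: 100000.0,  T_half: 14184.0}
  larva:  {rho25: 0.2088, deltaH_A: 26018.0, deltaH_H: 55990.0,   T_half: 304.6}
  pupa:   {rho25: 0.384,  deltaH_A: 14931.0, deltaH_H: -472379.0, T_half: 148.0}
gonotrophic: {rho25: 0.216, deltaH_A: 15725.0, deltaH_H: 1756481.0, T_half: 447.2}
mortality:
  # larval/pupal above-threshold response reflects the steep decline of
  # immature survival above ~30 C water temperature; through the
  # carrying-capacity rule (density dependence = 10 x mean larval
  # mortality) it also sets the strength of density-dependent
  # compensation, and with it the ~2-month rebound of adult abundance
  # after a non-residual adulticide campaign.  Eggs are
  # desiccation-resistant and respond much less.
  egg:   {base: 0.011, thr_hi: 30.0, coef_hi: 0.010, scale_hi: 4.0, thr_lo: 14.0, coef_lo: 0.033, scale_lo: 2.7035}
  larva: {base: 0.010, thr_hi: 30.0, coef_hi: 0.040, scale_hi: 3.0, thr_lo: 14.0, coef_lo: 0.033, scale_lo: 2.7035}
  pupa:  {base: 0.010, thr_hi: 30.0, coef_hi: 0.040, scale_hi: 3.0, thr_lo: 14.0, coef_lo: 0.033, scale_lo: 2.7035}
  adult: {base: 0.091, thr_hi: 39.0, coef_hi: 0.010, scale_hi: 2.0, thr_lo: 10.0, coef_lo: 0.050, scale_lo: 3.0}
water:
  # container water is buffered below the air minimum, tracks the mean,
  # and -- in partly sun-exposed containers -- peaks several degrees C
  # above the air maximum
  mean: {intercept: 3.5, slope: 0.87, sun: 2.0}
  min:  {intercept: 5.0, slope: 0.83, sun: 0.0}
  max:  {intercept: 2.0, slope: 0.98, sun: 12.0}
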