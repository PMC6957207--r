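# Rate set for the 9-state-1-step CaM-CaMKII model.
#
# CaM states are indexed by (N-lobe Ca2+, C-lobe Ca2+) occupancy, each
# 0-2; (0,0) is apo-CaM, (2,2) is fully saturated CaM4.
#
# Anchored values (printed in the source literature):
#   K_D(CaM_2C (0,2) - CaMKII) = 7.4e-6 M
#   K_D(apo-CaM (0,0) - CaMKII) = 1.45e-3 M
#   trapping_factor = 1000 (pT286 subunits bind every CaM state
#     1000-fold tighter; applied to koff), giving
#     K_D(apo-CaM - pT286 CaMKII) = 1.45e-6 M
#   K_D(PP1 - CaMKII) = 0.166e-6 M (k_off_PP / k_on_PP of the shared
#     phosphatase rates, 0.5 / 3e6)
#
# All other entries are SYNTHETIC placeholders chosen to be
# literature-plausible (source: Pepke2010 Fig2C; transcribe the measured
# values there to replace them). Per-lobe Ca2+ rates are sequential
# (first, second site); "bound" rates apply while CaM is CaMKII-bound.
ca_lobe:
  "N":
    free:  {kon: [1.0e+8, 1.0e+8], koff: [2.0e+4, 5.0e+2]}   # source: Pepke2010 Fig2C (synthetic placeholder)
    bound: {kon: [1.0e+8, 1.0e+8], koff: [2.0e+3, 5.0e+1]}   # source: Pepke2010 Fig2C (synthetic placeholder)
  "C":
    free:  {kon: [2.3e+7, 2.3e+7], koff: [2.4e+3, 2.4e+1]}   # source: Pepke2010 Fig2C (synthetic placeholder)
    bound: {kon: [2.3e+7, 2.3e+7], koff: [2.4e+2, 2.4e+0]}   # source: Pepke2010 Fig2C (synthetic placeholder)
# CaM-CaMKII one-step binding, keyed "nN.cC" by lobe occupancy.
# kon in M^-1 s^-1, koff in s^-1 (untrapped). Anchored: 0.0 (apo) and
# 0.2 (CaM_2C); others synthetic (source: Pepke2010 Fig2C).
camkii_binding:
  "0.0": {kon: 2.0e+4, koff: 2.9e+1}    # K_D 1.45e-3 M (anchor)
  "0.1": {kon: 5.0e+5, koff: 2.5e+1}
  "0.2": {kon: 1.0e+6, koff: 7.4e+0}    # K_D 7.4e-6 M (anchor, CaM_2C)
  "1.0": {kon: 1.0e+5, koff: 2.0e+1}
  "1.1": {kon: 1.0e+6, koff: 2.0e+1}
  "1.2": {kon: 5.0e+6, koff: 5.0e+0}
  "2.0": {kon: 5.0e+5, koff: 5.0e+1}
  "2.1": {kon: 5.0e+6, koff: 2.5e+1}
  "2.2": {kon: 5.0e+7, koff: 1.5e+0}    # K_D 3e-8 M (synthetic)
trapping_factor: 1000
trap_sub_saturated: true
autophos_rate: 1.0
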