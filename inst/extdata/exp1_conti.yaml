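# Experiment 1, continuously fed reactor: 6 L working volume, HRT 5.5 d,
# 37.2 gCOD/L VFA medium (45/10/45 acetic/propionic/butyric on COD basis).
# Influent inorganic carbon/nitrogen and kLa are calibrated values; see the
# methods vignette.
name: exp1_conti
reactor:
  V_liq: 6
  V_gas: 0.6
  HRT: 5.5
  T: 310.15
influent:
  type: vfa
  total_cod: 37.2
  cod_fractions: {ac: 0.45, pro: 0.10, bu: 0.45}
  S_IC_in: 0.010
  S_IN_in: 0.056
  S_cat_in: 0.0783
  S_an_in: 0.0198
kinetics:
  preset: this_study
  kLa: 50
feeding:
  regime: continuous
initial:
  inoculum_vs: 0.87
  partition: {X_su: 0.02, X_aa: 0.02, X_fa: 0.01, X_c4: 0.16, X_pro: 0.06,
              X_ac1: 0.03, X_ac2: 0.46, X_h2: 0.24}
  solubles: {S_ac: 0.10, S_pro: 0.05, S_bu: 0.10, S_IC: 0.10, S_IN: 0.045,
             S_cat: 0.0783, S_an: 0.0198}
t_end: 64
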