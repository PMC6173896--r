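# Maize-silage digester, HRT 20 d, fed every second day. Substrate
# characterization (COD fractions, ion background) follows a standard
# literature characterization of ensiled maize; editable.
name: maize_disco
reactor:
  V_liq: 6
  V_gas: 0.6
  HRT: 20
  T: 310.15
influent:
  type: composite
  total_cod: 80
  cod_fractions: {ch: 0.60, pr: 0.12, li: 0.07, xi: 0.16, si: 0.05}
  S_IC_in: 0.010
  S_IN_in: 0.005
  S_cat_in: 0.040
  S_an_in: 0.010
kinetics:
  preset: this_study
  kLa: 50
feeding:
  regime: discontinuous
  pulse_fraction: 1.0
  period: 2
  pulse_duration: 0.0138888888888888889
initial:
  inoculum_vs: 2.0
  partition: {X_su: 0.15, X_aa: 0.06, X_fa: 0.04, X_c4: 0.12, X_pro: 0.08,
              X_ac1: 0.0705, X_ac2: 0.30, X_h2: 0.1795}
  solubles: {S_ac: 0.10, S_IC: 0.08, S_IN: 0.03, S_cat: 0.040, S_an: 0.010}
t_end: 365
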