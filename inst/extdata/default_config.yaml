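# Calibrated default configuration (see the methods vignette and
# scripts/calibrate.R for how the free values were frozen).
# Units: mV / pF / GOhm / ms; rates in kHz.
membrane:
  cm0_pF: 26.67        # so that -15% is a 4 pF drop
  rm_GOhm: 1.0         # typical HEK-293 whole-cell input resistance
  vr_mV: -60
  vs0_mV: 15           # calibrated baseline surface potential
photoswitch:
  dcm_rel: -0.15       # reference capacitance amplitude
  dvs_mV: 5            # reference surface-potential amplitude
  tau_on_c_ms: 0.9     # calibrated
  tau_off_c_ms: 100    # calibrated
  tau_on_s_ms: 4       # calibrated
  tau_off_s_ms: 30     # calibrated
dipole:
  mu_trans_D: 1.05
  mu_cis_D: 7.35       # +6.3 D on isomerization
  leaflet: outer
  orientation: away_from_core
  coupling_mV_per_D: 1.25   # 4 D -> 5 mV reference calibration
  field_scaling_enabled: true
  vref_mV: -60
protocol:
  t_on_ms: 50
  duration_ms: 20
  wavelength_nm: 470
  irradiance_mW_mm2: 50
simulation:
  window_ms: 500
  rate_kHz: 20
  rtol: 1.0e-8
  atol: 1.0e-10
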