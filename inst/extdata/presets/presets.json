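{
  "comment": "Ground-truth parameters for synthetic adenine-thymine duplex datasets. Decay-model amplitudes are solved at load time by the deterministic calibration in presets.R from the window-fraction targets below.",
  "irf_fwhm_ps": 80,
  "grid": {"start": -1.0, "stop": 10.5, "bin_width": 0.025},
  "systems": {
    "pApT": {
      "spectrum": {
        "peak_nm": 327, "fwhm_cm1": 5400, "ratio_305_420": 3.9,
        "vis_center_nm": 425, "vis_fwhm_cm1": 3000
      },
      "quantum_yield": 3e-4
    },
    "A20T20": {
      "spectrum": {
        "peak_nm": 327, "fwhm_cm1": 6900, "ratio_305_420": 2.659,
        "vis_center_nm": 425, "vis_fwhm_cm1": 3000
      },
      "quantum_yield": 3e-4
    }
  },
  "anisotropy": {
    "pApT": {
      "305": {"r_inf": 0.02, "components": [{"amplitude": 0.181432, "correlation_time": 0.3}]},
      "420": {"r_inf": 0.02, "components": [{"amplitude": -0.012, "correlation_time": 0.6}]}
    },
    "A20T20": {
      "305": {"r_inf": 0.04, "components": [{"amplitude": 0.153519, "correlation_time": 0.3}]},
      "420": {"r_inf": 0.02, "components": [{"amplitude": -0.08, "correlation_time": 0.5}]}
    }
  },
  "melting": {
    "pApT.standard": {"tm": 72, "width": 1.5, "a_folded_ref": 1.0, "hyperchromicity_pct": 70, "baseline_slopes": [0.0004, 0.0004]},
    "pApT.KCl_matched": {"tm": 72, "width": 1.5, "a_folded_ref": 1.0, "hyperchromicity_pct": 70, "baseline_slopes": [0.0004, 0.0004]},
    "pApT.diluted_6x": {"tm": 65, "width": 2.0, "a_folded_ref": 1.0, "hyperchromicity_pct": 60, "baseline_slopes": [0.0004, 0.0004]},
    "A20T20.standard": {"tm": 63, "width": 2.5, "a_folded_ref": 1.0, "hyperchromicity_pct": 40, "baseline_slopes": [0.0004, 0.0004]}
  },
  "presets": {
    "pApT.267.standard": {
      "mode": "spectral",
      "wavelength_start": 305, "wavelength_stop": 440, "wavelength_step": 5,
      "tau_long_anchor_nm": [305, 440], "tau_long_anchor_ns": [2.6, 2.2],
      "budget_after1": 0.15, "budget_mid": 0.20,
      "vu_ratio": 0.20, "R_target": 5.6,
      "long_uv_fwhm_cm1": 8000, "long_vis_center_nm": 425, "long_vis_fwhm_cm1": 2200,
      "mid_center_nm": 320, "mid_fwhm_cm1": 8000,
      "mid_vis_center_nm": 425, "mid_vis_fwhm_cm1": 3000, "mid_vis_height": 0.12,
      "background_rate": 2.0
    },
    "pApT.267.KCl_matched": {"alias_decays": "pApT.267.standard"},
    "pApT.267.diluted_6x": {"base": "pApT.267.standard", "fraction_scale": 1.1527},
    "pApT.285.standard": {
      "mode": "anchors",
      "wavelengths": [305, 330, 420],
      "f_after1": [0.275, 0.125, 0.28],
      "g_mid": [0.20, 0.22, 0.30],
      "tau_long": [2.2, 2.15, 2.0],
      "background_rate": 2.0
    },
    "pApT.285.KCl_matched": {"alias_decays": "pApT.285.standard"},
    "pApT.285.diluted_6x": {
      "mode": "anchors",
      "wavelengths": [305, 330, 420],
      "f_after1": [0.317, 0.157, 0.323],
      "g_mid": [0.20, 0.22, 0.30],
      "tau_long": [2.2, 2.15, 2.0],
      "background_rate": 2.0
    },
    "A20T20.285.standard": {
      "mode": "anchors",
      "wavelengths": [305, 330, 420],
      "f_after1": [0.501, 0.306, 0.36],
      "g_mid": [0.22, 0.25, 0.34],
      "tau_long": [2.7, 2.6, 2.4],
      "background_rate": 2.0
    }
  }
}
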