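{
  "comment": "Bundled preset catalog. Dye photophysics and lineshape parameters are representative literature-style values chosen for self-contained operation; they are documented artifact choices, not measured spectra. Synthetic in that sense. The fluorescein natural lifetime of 4 ns matches its well-known free-dye value.",
  "grid_nm": {"from": 300, "to": 900, "by": 1},
  "dyes": {
    "fluorescein": {
      "Q0": 0.93, "tau0_ns": 4.0,
      "emission":   {"peak_nm": 520, "fwhm_nm": 38, "shape": "gaussian"},
      "absorption": {"peak_nm": 494, "fwhm_nm": 32, "shape": "gaussian"}
    },
    "rhodamine_green": {
      "Q0": 0.92, "tau0_ns": 4.1,
      "emission":   {"peak_nm": 527, "fwhm_nm": 40, "shape": "gaussian"},
      "absorption": {"peak_nm": 502, "fwhm_nm": 30, "shape": "gaussian"}
    },
    "rhodamine_red": {
      "Q0": 0.88, "tau0_ns": 3.5,
      "emission":   {"peak_nm": 590, "fwhm_nm": 42, "shape": "gaussian"},
      "absorption": {"peak_nm": 570, "fwhm_nm": 32, "shape": "gaussian"}
    }
  },
  "nanostructures": {
    "GNP_r10":   {"material": "Au", "h_nm": 20, "R_nm": 10},
    "SNP_r10":   {"material": "Ag", "h_nm": 20, "R_nm": 10},
    "GNR_40x20": {"material": "Au", "h_nm": 40, "R_nm": 10},
    "SNR_40x20": {"material": "Ag", "h_nm": 40, "R_nm": 10},
    "GNR_60x25": {"material": "Au", "h_nm": 60, "R_nm": 12.5}
  }
}
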