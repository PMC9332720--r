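{
  "country": "Toyland",
  "year": 2020,
  "source": "lexrisk toy fixture (synthetic)",
  "age_grid": [0, 1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95],
  "files": ["manifest.json", "diseases.csv", "death_rates.csv", "risk_factors.csv", "exposures.csv", "rr_functions.csv", "mediation.csv", "lags.csv"]
}
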