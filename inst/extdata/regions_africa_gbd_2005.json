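{
  "dataset": "africa_gbd_2005",
  "unit": "percent",
  "description": "Regional inputs for the five Global Burden of Disease (GBD) regions of Africa, reference year 2005: proportion of people in need of antiretroviral therapy receiving it (with 95% bounds), and prevalence of current drinkers by sex and age band.",
  "coverage_source": "UNAIDS, 2006 Report on the Global AIDS Epidemic (2005 data); regional values are population-weighted averages of country-level coverage.",
  "drinkers_source": "WHO survey data on current drinkers (any alcohol consumption within the reference period), 2005.",
  "age_bands": ["15-34", "35-54", "55+"],
  "regions": [
    {
      "region": "North Africa/Middle East",
      "coverage": {"lower": 15.01, "value": 17.36, "upper": 19.71},
      "drinkers": [
        {"sex": "men", "age_band": "15-34", "value": 7.2},
        {"sex": "men", "age_band": "35-54", "value": 12.0},
        {"sex": "men", "age_band": "55+", "value": 5.5},
        {"sex": "women", "age_band": "15-34", "value": 3.5},
        {"sex": "women", "age_band": "35-54", "value": 1.1},
        {"sex": "women", "age_band": "55+", "value": 0.4}
      ]
    },
    {
      "region": "Sub-Saharan Africa, Central",
      "coverage": {"lower": 3.00, "value": 4.25, "upper": 5.50},
      "drinkers": [
        {"sex": "men", "age_band": "15-34", "value": 51.0},
        {"sex": "men", "age_band": "35-54", "value": 51.9},
        {"sex": "men", "age_band": "55+", "value": 20.5},
        {"sex": "women", "age_band": "15-34", "value": 32.4},
        {"sex": "women", "age_band": "35-54", "value": 28.5},
        {"sex": "women", "age_band": "55+", "value": 11.9}
      ]
    },
    {
      "region": "Sub-Saharan Africa, East",
      "coverage": {"lower": 12.07, "value": 14.24, "upper": 16.41},
      "drinkers": [
        {"sex": "men", "age_band": "15-34", "value": 24.6},
        {"sex": "men", "age_band": "35-54", "value": 38.8},
        {"sex": "men", "age_band": "55+", "value": 37.2},
        {"sex": "women", "age_band": "15-34", "value": 16.1},
        {"sex": "women", "age_band": "35-54", "value": 24.9},
        {"sex": "women", "age_band": "55+", "value": 21.4}
      ]
    },
    {
      "region": "Sub-Saharan Africa, South",
      "coverage": {"lower": 19.11, "value": 21.67, "upper": 24.22},
      "drinkers": [
        {"sex": "men", "age_band": "15-34", "value": 38.0},
        {"sex": "men", "age_band": "35-54", "value": 38.0},
        {"sex": "men", "age_band": "55+", "value": 29.5},
        {"sex": "women", "age_band": "15-34", "value": 12.6},
        {"sex": "women", "age_band": "35-54", "value": 15.7},
        {"sex": "women", "age_band": "55+", "value": 9.8}
      ]
    },
    {
      "region": "Sub-Saharan Africa, West",
      "coverage": {"lower": 11.36, "value": 13.47, "upper": 15.59},
      "drinkers": [
        {"sex": "men", "age_band": "15-34", "value": 36.2},
        {"sex": "men", "age_band": "35-54", "value": 50.9},
        {"sex": "men", "age_band": "55+", "value": 40.5},
        {"sex": "women", "age_band": "15-34", "value": 20.8},
        {"sex": "women", "age_band": "35-54", "value": 31.2},
        {"sex": "women", "age_band": "55+", "value": 27.1}
      ]
    }
  ]
}
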