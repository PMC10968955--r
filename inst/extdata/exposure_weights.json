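{
  "version": "1.0",
  "description": "Meta-analytic odds ratios and natural-log-odds weights for the ten binarized exposome components. printed_log_odds records the conventional 2-decimal values; weights used in scoring are recomputed as ln(odds_ratio) at full precision. For advanced paternal age the component-level entry is the 35-54-year tier; both tiers are listed under paternal_age_tiers.",
  "components": [
    {"component": "winter_birth", "odds_ratio": 1.05, "printed_log_odds": 0.05},
    {"component": "obstetric_complications", "odds_ratio": 2.00, "printed_log_odds": 0.69},
    {"component": "advanced_paternal_age", "odds_ratio": 1.28, "printed_log_odds": 0.25},
    {"component": "non_right_handedness", "odds_ratio": 1.65, "printed_log_odds": 0.50},
    {"component": "emotional_neglect", "odds_ratio": 2.90, "printed_log_odds": 1.06},
    {"component": "emotional_abuse", "odds_ratio": 3.40, "printed_log_odds": 1.22},
    {"component": "bullying", "odds_ratio": 2.39, "printed_log_odds": 0.87},
    {"component": "sexual_abuse", "odds_ratio": 2.38, "printed_log_odds": 0.87},
    {"component": "cannabis_use", "odds_ratio": 1.75, "printed_log_odds": 0.56},
    {"component": "urban_upbringing", "odds_ratio": 1.72, "printed_log_odds": 0.54}
  ],
  "paternal_age_tiers": [
    {"tier": "35-54", "odds_ratio": 1.28, "printed_log_odds": 0.25},
    {"tier": ">=55", "odds_ratio": 2.22, "printed_log_odds": 0.80}
  ]
}
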