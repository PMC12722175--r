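# Example threshold-rule configuration in the structural style of the
# Swedish nephrology referral criteria (fixed thresholds of age, eGFR and
# albuminuria). The numeric thresholds below are PLACEHOLDERS chosen to be
# clinically plausible; they are NOT an authoritative transcription of the
# Swedish criteria. Replace with locally valid thresholds before applied use.
name: swedish_example
clauses:
  - egfr_below: 30
  - egfr_below: 45
    age_below: 70
  - acr_at_least: 300
  - acr_at_least: 100
    age_below: 60
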