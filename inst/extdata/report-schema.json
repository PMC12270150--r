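{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "efastress analysis report",
  "type": "object",
  "required": ["report_type", "tests", "provenance"],
  "confound_required": [
    "group_summaries", "combined_summaries", "underestimation",
    "underestimation_per_experiment", "condition_effects", "dose_response"
  ],
  "atp_required": ["atp_budget", "atp_per_experiment"],
  "properties": {
    "report_type": {"enum": ["confound", "atp"]},
    "group_summaries": {"type": "array"},
    "combined_summaries": {"type": "array"},
    "underestimation": {"type": "array"},
    "underestimation_per_experiment": {"type": "array"},
    "condition_effects": {"type": "array"},
    "dose_response": {"type": "array"},
    "atp_budget": {"type": "array"},
    "atp_per_experiment": {"type": "array"},
    "tests": {"type": "array"},
    "provenance": {"type": "object"}
  }
}
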